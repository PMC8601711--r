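# One-to-one minimum-cost assignment on a sparse candidate set.
#
# Both stereo pairing and frame-to-frame linking reduce to small rectangular
# assignment problems where many pairings are forbidden (gating by residual,
# step length or speed). Problems are tiny (a handful of targets per frame),
# so an exact branch-and-bound search is used; a greedy pass supplies the
# initial bound and is the fallback above a size cap.

#' Minimum-cost one-to-one assignment over allowed pairs
#'
#' @param cost numeric matrix (rows = one side, columns = other); `NA` or
#'   `Inf` entries mark forbidden pairings. Not every row/column need be
#'   matched: unmatched items incur zero cost, so the solver minimises total
#'   cost over all maximal sets of allowed pairings. Because leaving a pair
#'   unmatched is never cheaper than any allowed (finite-cost) pairing being
#'   required downstream, the search maximises the number of matches first,
#'   then minimises cost among maximum matchings.
#' @param exact_max maximum number of rows for the exact search (default 12);
#'   larger problems fall back to greedy matching.
#' @return integer vector of length `nrow(cost)`; entry i is the matched
#'   column for row i, or `NA` if row i is unmatched.
#' @keywords internal
solve_assignment <- function(cost, exact_max = 12L) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  cost[!is.finite(cost)] <- NA_real_

  greedy <- function() {
    match <- rep(NA_integer_, nr)
    used <- rep(FALSE, nc)
    ord <- order(cost, na.last = NA)
    for (k in ord) {
      i <- ((k - 1) %% nr) + 1L
      j <- ((k - 1) %/% nr) + 1L
      if (is.na(match[i]) && !used[j]) {
        match[i] <- j
        used[j] <- TRUE
      }
    }
    match
  }

  g <- greedy()
  if (nr > exact_max) return(g)

  best_n <- sum(!is.na(g))
  best_cost <- sum(cost[cbind(which(!is.na(g)), g[!is.na(g)])])
  best <- g

  # order rows by number of options (most constrained first)
  nopt <- apply(cost, 1, function(r) sum(!is.na(r)))
  row_ord <- order(nopt)
  match <- rep(NA_integer_, nr)
  used <- rep(FALSE, nc)

  recurse <- function(k, n_matched, acc) {
    if (k > nr) {
      if (n_matched > best_n || (n_matched == best_n && acc < best_cost - 1e-12)) {
        best_n <<- n_matched; best_cost <<- acc; best <<- match
      }
      return(invisible(NULL))
    }
    # bound: even matching every remaining row cannot beat best_n
    if (n_matched + (nr - k + 1) < best_n) return(invisible(NULL))
    i <- row_ord[k]
    js <- which(!is.na(cost[i, ]) & !used)
    if (length(js)) js <- js[order(cost[i, js])]
    for (j in js) {
      c_ij <- cost[i, j]
      if (n_matched + 1 + (nr - k) < best_n) break
      match[i] <<- j; used[j] <<- TRUE
      recurse(k + 1, n_matched + 1, acc + c_ij)
      match[i] <<- NA_integer_; used[j] <<- FALSE
    }
    # leave row i unmatched
    recurse(k + 1, n_matched, acc)
  }
  recurse(1L, 0L, 0)
  best
}
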