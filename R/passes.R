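# Acoustic event bookkeeping: pass counting from call timestamps, the
# 5-min block aggregation with first-minute exclusion, composition
# summaries, and raw percent reductions.

#' Count bat passes from call timestamps
#'
#' A new pass starts whenever the gap since the previous call exceeds the
#' separation threshold (1 s as published).
#'
#' @param timestamps sorted numeric call times, seconds.
#' @param gap_s pass-separation threshold, s.
#' @return integer pass count.
#' @export
count_passes <- function(timestamps, gap_s = 1) {
  if (!length(timestamps)) return(0L)
  if (is.unsorted(timestamps))
    stop("'timestamps' must be sorted", call. = FALSE)
  sum(diff(timestamps) > gap_s) + 1L
}

#' Aggregate per-10-s-file counts into 5-min blocks
#'
#' Each 5-min block comprises thirty 10 s files; the first minute (files
#' 1-6) is excluded to minimise spill-over from the previous block, leaving
#' twenty-four files whose counts are summed per block and series.
#'
#' @param files data.frame with columns `site`, `night`, `block`,
#'   `file_index` (1-30 within block), `count`, plus any grouping columns
#'   (e.g. `species_group`, `event`, `treatment`) preserved in the output.
#' @param files_per_block expected files per block (default 30).
#' @param exclude_first number of leading files dropped per block
#'   (default 6).
#' @return data.frame with one row per block and grouping combination,
#'   `count` holding the block total.
#' @export
aggregate_blocks <- function(files, files_per_block = 30, exclude_first = 6) {
  need <- c("site", "night", "block", "file_index", "count")
  miss <- setdiff(need, names(files))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  grp_cols <- setdiff(names(files), c("file_index", "count"))
  key <- interaction(files[grp_cols], drop = TRUE)
  bad <- names(which(tapply(files$file_index, key, function(ix)
    length(ix) != files_per_block || !setequal(ix, seq_len(files_per_block)))))
  if (length(bad))
    stop("block(s) without exactly ", files_per_block, " files: ",
         paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
  keep <- files$file_index > exclude_first
  agg <- stats::aggregate(count ~ ., data = files[keep,
    c(grp_cols, "count"), drop = FALSE], FUN = sum)
  agg
}

#' Species composition table
#'
#' Per-species totals, percentages of the grand total (2 d.p.) and per-night
#' means.
#'
#' @param counts data.frame with `species_group`, `count` and (for per-night
#'   means) `night`.
#' @param n_nights number of nights (default: distinct `night` values).
#' @return data.frame `species_group`, `total`, `percent`, `per_night_mean`,
#'   ordered by decreasing total; attribute `grand_total`.
#' @export
composition_table <- function(counts, n_nights = NULL) {
  tot <- tapply(counts$count, counts$species_group, sum)
  grand <- sum(tot)
  n_nights <- n_nights %||% length(unique(counts$night))
  out <- data.frame(species_group = names(tot),
                    total = as.integer(tot),
                    percent = round(100 * as.numeric(tot) / grand, 2),
                    per_night_mean = as.numeric(tot) / n_nights)
  out <- out[order(-out$total), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, grand_total = grand)
}

#' Percent reduction of counts under the deterrent
#'
#' Raw reduction `100 * (1 - total_deterrent / total_control)`; when a model
#' coefficient is supplied the model-based reduction
#' `100 * (1 - exp(beta))` is reported alongside.
#'
#' @param blocks data.frame with `treatment` (`"control"`/`"deterrent"`) and
#'   `count`; pre-filter to the species/event selection of interest.
#' @param beta_treatment optional log-scale treatment coefficient from a
#'   count model.
#' @return named numeric: `raw_percent` (signed; negative = increase) and,
#'   if `beta_treatment` given, `model_percent`.
#' @export
percent_reduction <- function(blocks, beta_treatment = NULL) {
  tc <- sum(blocks$count[blocks$treatment == "control"])
  td <- sum(blocks$count[blocks$treatment == "deterrent"])
  if (tc == 0 || !any(blocks$treatment == "deterrent") ||
      !any(blocks$treatment == "control"))
    stop("both treatment arms must be present with nonzero control total",
         call. = FALSE)
  out <- c(raw_percent = 100 * (1 - td / tc))
  if (!is.null(beta_treatment))
    out <- c(out, model_percent = 100 * (1 - exp(beta_treatment)))
  out
}
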