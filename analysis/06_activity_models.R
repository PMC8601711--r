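#!/usr/bin/env Rscript
# Stage 6: block-design count analysis — species composition, raw and
# model-based percent reductions, and Poisson/negative-binomial GLMMs with
# treatment + block order fixed effects and block-in-night-in-site random
# intercepts.

suppressMessages(library(stereobat))

counts <- read_csv_checked("results/counts.csv",
                           c("site", "night", "block", "treatment",
                             "series", "species_group", "event", "count"))

passes <- counts[counts$event == "pass", ]
comp <- composition_table(passes)
write.csv(comp, "results/composition.csv", row.names = FALSE)
cat("species composition of passes:\n"); print(comp)
cat(sprintf("grand total %d passes, %.2f per night\n",
            attr(comp, "grand_total"), attr(comp, "grand_total") / 9))

overall <- percent_reduction(passes)
cat(sprintf("overall raw activity reduction: %.2f%%\n",
            overall[["raw_percent"]]))

res <- NULL
for (s in unique(counts$series)) {
  cb <- counts[counts$series == s, ]
  m <- tryCatch(suppressWarnings(fit_count_model(cb)),
                error = function(e) {
                  cat(sprintf("  %s: %s\n", s, conditionMessage(e)))
                  NULL
                })
  if (is.null(m)) next
  pr <- m$percent_reduction
  cat(sprintf("  %s [%s]: rate ratio %.3f, reduction raw %.1f%% / model %.1f%%, LRT p = %.3g\n",
              s, m$family, m$rate_ratio, pr[["raw_percent"]],
              pr[["model_percent"]], m$p))
  res <- rbind(res, data.frame(series = s, family = m$family,
                               rate_ratio = m$rate_ratio,
                               raw_percent = pr[["raw_percent"]],
                               model_percent = pr[["model_percent"]],
                               chisq = m$lrt_chisq, df = m$lrt_df, p = m$p))
}
write.csv(res, "results/count_models.csv", row.names = FALSE)
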