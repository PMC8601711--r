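#!/usr/bin/env Rscript
# Stage 7: echolocation call-parameter LMMs — treatment, block order and
# number of bats as fixed effects, site/night/block-pair/time-block/
# sequence nested random intercepts, Bonferroni correction over the six
# responses tested on the same call data.

suppressMessages(library(stereobat))

calls <- read_csv_checked("results/call_params.csv",
                          c("site", "night", "block_pair", "time_block",
                            "sequence", "treatment", "n_bats", "bandwidth",
                            "start_frequency", "end_frequency", "fmaxe",
                            "duration", "pulse_interval"))
responses <- c("bandwidth", "start_frequency", "end_frequency", "fmaxe",
               "duration", "pulse_interval")
res <- NULL
for (r in responses) {
  m <- suppressWarnings(suppressMessages(fit_call_param_model(calls, r)))
  est <- m$fixed$estimate[m$fixed$term == "treatmentdeterrent"]
  cat(sprintf("  %s: treatment effect %+.2f kHz/ms, p = %.3g (adjusted %.3g)\n",
              r, est, m$p, m$p_adjusted))
  res <- rbind(res, data.frame(response = r, estimate = est,
                               chisq = m$lrt_chisq, p = m$p,
                               p_adjusted = m$p_adjusted))
}
write.csv(res, "results/call_models.csv", row.names = FALSE)
sig <- res$response[res$p_adjusted < 0.05]
cat("significant after Bonferroni:", paste(sig, collapse = ", "), "\n")
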