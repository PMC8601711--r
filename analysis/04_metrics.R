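#!/usr/bin/env Rscript
# Stage 4: per-trajectory flight variables (speed, length, net
# displacement, tortuosity, range and height), compared against the same
# variables computed on the ground-truth paths.

suppressMessages(library(stereobat))

td <- read_csv_checked("results/trajectories.csv",
                       c("trajectory_id", "frame", "x", "y", "z"))
est <- trajectory_metrics(split(td, td$trajectory_id))
write.csv(est, "results/metrics.csv", row.names = FALSE)

gt <- read.csv("results/scene/ground_truth.csv")
truth <- trajectory_metrics(split(gt, gt$path_id))

cat("recovered trajectory metrics:\n")
print(est[, c("trajectory_id", "mean_speed", "total_length",
              "tortuosity_value", "distance_from_deterrent",
              "mean_height")], digits = 3)
# match recovered to truth by mean range for the audit
est_m <- est[order(est$mean_y), ]
tr_m <- truth[order(truth$mean_y), ]
n <- min(nrow(est_m), nrow(tr_m))
cat(sprintf("speed recovery: max abs error %.3f m/s over %d matched trajectories\n",
            max(abs(est_m$mean_speed[1:n] - tr_m$mean_speed[1:n])), n))
cat(sprintf("tortuosity recovery: max abs error %.4f\n",
            max(abs(est_m$tortuosity_value[1:n] - tr_m$tortuosity_value[1:n]))))
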