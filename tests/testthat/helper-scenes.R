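# Shared fixtures: rigs, small synthetic scenes and ground-truth
# localisation tables, all generated in code under fixed seeds.

# quarter-resolution rig for fast rendering tests (same FOV as the field rig)
small_rig <- function() stereo_rig(image_size = c(320L, 240L))

# noiseless 3D localisations taken straight from ground-truth paths,
# tagged with the generating path id
gt_localisations <- function(paths) {
  do.call(rbind, lapply(seq_along(paths), function(i)
    data.frame(frame = paths[[i]]$frame, x = paths[[i]]$x,
               y = paths[[i]]$y, z = paths[[i]]$z,
               residual = 0, truth_path = i)))
}

# straight-line constant-speed path (default along +y)
straight_path <- function(n = 10, speed = 5, dt = 0.032,
                          start = c(2000, 10000, 0),
                          direction = c(0, 1, 0)) {
  step <- speed * dt * 1000 * direction / sqrt(sum(direction^2))
  structure(
    data.frame(frame = 0:(n - 1),
               x = start[1] + step[1] * (0:(n - 1)),
               y = start[2] + step[2] * (0:(n - 1)),
               z = start[3] + step[3] * (0:(n - 1)), regime = "commuting"),
    dt = dt, responded = FALSE,
    class = c("ground_truth_path", "data.frame"))
}

# partition of localisation rows implied by a list of trajectories,
# canonicalised for comparison
partition_of <- function(trajs) {
  sets <- lapply(trajs, function(tr)
    sort(paste(tr$frame, round(tr$x, 6), round(tr$y, 6), round(tr$z, 6))))
  sets[order(vapply(sets, `[`, "", 1))]
}

# bats kept well inside the joint field of view; diagonal headings so the
# projected blobs sweep across pixels (keeps the median background clean)
test_paths <- function(n_bats = 3, n_frames = 20, seed = 42) {
  starts <- list(c(1200, 11000, 300), c(2800, 15000, -400),
                 c(2000, 18000, 700))
  headings <- c(pi / 4, 3 * pi / 4, pi / 3)
  lapply(seq_len(n_bats), function(i)
    simulate_trajectory(flight_regime(if (i == 2) "foraging" else "commuting"),
                        n_frames, seed = seed + i,
                        start = starts[[i]], heading0 = headings[i]))
}

suppress_fit_noise <- function(expr) {
  withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) {
      if (grepl("boundary|singular|NA/NaN|Model convergence|false convergence",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
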