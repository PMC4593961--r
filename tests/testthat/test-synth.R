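test_that("spatial_weights matches the closed-form Gaussian profile", {
  g <- build_grid(7, 9)
  cp <- compartment("index", center = c(55, 60), spread = c(12, 10),
                    gain = 2.5)
  w <- spatial_weights(cp, g)
  # elementwise closed-form oracle
  manual <- numeric(63)
  for (ch in 1:63) {
    co <- channel_coordinates(g, ch)
    manual[ch] <- 2.5 * exp(-(co[["x"]] - 55)^2 / (2 * 144) -
                             (co[["y"]] - 60)^2 / (2 * 100))
  }
  expect_equal(w, manual)
  # a channel at the exact center carries weight = gain
  g2 <- build_grid(2, 3, c(40, 70))  # has a channel at (55, 75)
  cp2 <- compartment("x", center = c(55, 75), spread = c(5, 5), gain = 3)
  expect_equal(max(spatial_weights(cp2, g2)), 3)
  # far channels (>= 5 sd) are essentially zero
  cp3 <- compartment("x", center = c(0, 0), spread = c(3, 3), gain = 1)
  far <- g$channels$x > 15 & g$channels$y > 15
  expect_true(all(spatial_weights(cp3, g)[far] < exp(-12.5)))
})

test_that("the default layout encodes the compartment geography", {
  cps <- default_compartments()
  expect_gt(cps$index$center[2], cps$ring$center[2])   # index distal
  expect_lt(cps$middle$center[2], cps$ring$center[2])  # middle proximal
  expect_lt(abs(cps$ring$center[2] - cps$little$center[2]), 10)
  ens <- default_enslaving()
  expect_equal(unname(diag(ens[1:4, ])), rep(1, 4))
  expect_equal(unname(ens["four", ]), rep(1, 4))
  expect_true(all(ens >= 0))
})

test_that("true_activation_rms composes compartments root-sum-of-squares", {
  cfg <- simulation_config(noise_rms = 0)
  fingers <- colnames(cfg$enslaving)
  w <- sapply(fingers, function(f)
    spatial_weights(cfg$compartments[[f]], cfg$grid))
  for (task in c("index", "four")) {
    manual <- sqrt(rowSums(
      (w * matrix(cfg$enslaving[task, ], 63, 4, byrow = TRUE))^2))
    expect_equal(true_activation_rms(cfg, task, "high", "static"), manual)
  }
  # effort scales amplitudes linearly
  expect_equal(true_activation_rms(cfg, "index", "low", "static"),
               0.5 * true_activation_rms(cfg, "index", "high", "static"))
  # dynamic shift displaces the territory
  sh <- true_activation_rms(cfg, "index", "high", "dynamic")
  st <- true_activation_rms(cfg, "index", "high", "static")
  cy_dyn <- map_centroid(build_map(sh, cfg$grid))[["cy"]]
  cy_st <- map_centroid(build_map(st, cfg$grid))[["cy"]]
  expect_lt(cy_dyn, cy_st)  # default shift is proximal (negative y)
})

test_that("simulate_recording is seed-deterministic", {
  cfg <- single_compartment_config(noise_rms = 0.1, seed = 33)
  s1 <- simulate_recording(cfg, "index", "high", "static")
  s2 <- simulate_recording(cfg, "index", "high", "static")
  expect_identical(s1$recording$signal, s2$recording$signal)
  # different conditions and subjects draw different streams
  s3 <- simulate_recording(cfg, "index", "low", "static")
  expect_false(identical(s1$recording$signal[1, 1:100],
                         s3$recording$signal[1, 1:100]))
  s4 <- simulate_recording(cfg, "index", "high", "static", subject = 2)
  expect_false(identical(s1$recording$signal[1, 1:100],
                         s4$recording$signal[1, 1:100]))
})

test_that("protocol structure: windows, repetitions, rest-only segments", {
  cfg <- single_compartment_config(noise_rms = 0.05, seed = 12)
  sim <- simulate_recording(cfg, "index", "high", "static")
  rec <- sim$recording
  expect_equal(length(rec$trials), 3L)
  fs <- rec$fs
  for (tr in rec$trials) {
    expect_equal(diff(tr$active_window) + 1, 5 * fs)
    expect_equal(diff(tr$rest_window) + 1, 2 * fs)
    # rest window ends 0.25 s before contraction onset
    expect_equal(tr$active_window[1] - tr$rest_window[2],
                 0.25 * fs + 1)
  }
  # rest segments carry only baseline noise
  r1 <- rec$trials[[1]]$rest_window
  rest_rms <- apply(rec$signal[, r1[1]:r1[2]], 1, channel_rms)
  expect_true(all(rest_rms < 3 * cfg$noise_rms))
})

test_that("noise-free recovery: pipeline map matches configured weights", {
  cfg <- single_compartment_config(noise_rms = 0, seed = 5)
  sim <- simulate_recording(cfg, "index", "high", "static")
  rms <- condition_rms(emg_bandpass(sim$recording))
  w <- sim$truth$rms
  expect_equal(w, spatial_weights(cfg$compartments$index, cfg$grid))
  # active channels recovered within 5% after preprocessing
  act <- w > 0.05 * max(w)
  expect_lt(max(abs(rms[act] - w[act]) / w[act]), 0.05)
})

test_that("zero gain means no activation anywhere", {
  cfg <- single_compartment_config(noise_rms = 0.2, seed = 8)
  cfg$compartments$index$gain <- 1e-12
  sim <- simulate_recording(cfg, "index", "high", "static")
  rms <- condition_rms(emg_bandpass(sim$recording))
  expect_lt(max(rms), 0.015)
})

test_that("generate_cohort is deterministic and jitter-controlled", {
  cfg <- simulation_config(seed = 101)
  c1 <- generate_cohort(cfg, n_subjects = 3, seed = 101)
  c2 <- generate_cohort(cfg, n_subjects = 3, seed = 101)
  expect_identical(c1$subject_configs, c2$subject_configs)
  # zero jitter -> subjects share the template parameters
  c0 <- generate_cohort(cfg, n_subjects = 2, seed = 101,
                        jitter = list(center_sd = 0, gain_sd = 0,
                                      enslaving_sd = 0))
  expect_equal(c0$subject_configs[[1]]$compartments,
               cfg$compartments)
  expect_equal(c0$subject_configs[[2]]$enslaving, cfg$enslaving)
  # instructed-finger entries never jittered away from 1
  expect_true(all(vapply(c1$subject_configs, function(sc)
    all(diag(sc$enslaving[1:4, ]) == 1) && all(sc$enslaving["four", ] == 1),
    logical(1))))
  expect_equal(nrow(c1$design), 20L)
})

test_that("cohort pipeline recovers ground-truth centroids per finger", {
  res <- default_cohort_results()
  # group-mean recovered centroid within 2 percentage points of the
  # group-mean ground-truth centroid, per finger (high/dynamic cell)
  for (f in c("index", "middle", "ring", "little")) {
    sel <- res$summary$finger == f & res$summary$effort == "high" &
      res$summary$constraint == "dynamic"
    expect_lt(abs(mean(res$summary$cy[sel]) - mean(res$truth$cy[sel])), 2)
    expect_lt(abs(mean(res$summary$cx[sel]) - mean(res$truth$cx[sel])), 2)
  }
})

test_that("effort monotonicity: high beats low for every finger", {
  res <- default_cohort_results()
  s <- res$summary
  agg <- aggregate(mean_rms ~ finger + effort, s, mean)
  for (f in unique(agg$finger)) {
    expect_gt(agg$mean_rms[agg$finger == f & agg$effort == "high"],
              agg$mean_rms[agg$finger == f & agg$effort == "low"])
  }
})

test_that("dynamic shift displaces centroids and yields positive SSD", {
  res <- default_cohort_results()
  s <- res$summary
  # default shift is (0, -3): dynamic centroids sit proximal of static
  agg <- aggregate(cy ~ constraint, s[s$finger != "four", ], mean)
  expect_lt(agg$cy[agg$constraint == "dynamic"],
            agg$cy[agg$constraint == "static"])
  dys <- ssd_contrasts(res$maps, "dynamic_vs_static")
  expect_true(all(dys$ssd > 0))
})
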