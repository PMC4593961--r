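test_that("channel_rms closed forms and brute-force oracle", {
  expect_equal(channel_rms(rep(-3, 100)), 3)
  # unit sine over whole periods
  t <- seq(0, 1, length.out = 2001)[-2001]
  expect_equal(channel_rms(sin(2 * pi * 5 * t)), 1 / sqrt(2),
               tolerance = 1e-9)
  set.seed(3)
  x <- rnorm(10)
  acc <- 0
  for (v in x) acc <- acc + v * v
  expect_equal(channel_rms(x), sqrt(acc / 10))
  expect_error(channel_rms(numeric(0)), "non-empty")
})

test_that("RMS is scale-equivariant and non-negative", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(50)
    k <- rnorm(1) * 5
    expect_equal(channel_rms(k * x), abs(k) * channel_rms(x))
    expect_gte(channel_rms(x), 0)
  }
})

make_two_window_recording <- function(act_amp, rest_amp, n_ch = 2,
                                      fs = 2000) {
  # 4 s record: rest in [1,2] s region, active in [2.5, 3.5] s region
  n <- 4 * fs
  set.seed(99)
  sig <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    sig[ch, ] <- rnorm(n)
  }
  rest_w <- c(fs + 1, 2 * fs)
  act_w <- c(2.5 * fs + 1, 3.5 * fs)
  for (ch in seq_len(n_ch)) {
    sig[ch, rest_w[1]:rest_w[2]] <-
      sig[ch, rest_w[1]:rest_w[2]] /
      channel_rms(sig[ch, rest_w[1]:rest_w[2]]) * rest_amp[ch]
    sig[ch, act_w[1]:act_w[2]] <-
      sig[ch, act_w[1]:act_w[2]] /
      channel_rms(sig[ch, act_w[1]:act_w[2]]) * act_amp[ch]
  }
  trial <- task_trial("index", "high", "dynamic", act_w, rest_w)
  list(rec = emg_recording(sig, fs, trials = list(trial)), trial = trial)
}

test_that("baseline_corrected_rms subtracts rest RMS and floors at zero", {
  f <- make_two_window_recording(act_amp = c(5, 1), rest_amp = c(2, 1.5))
  out <- baseline_corrected_rms(f$trial, f$rec)
  expect_equal(out[1], 3, tolerance = 1e-9)
  expect_equal(out[2], 0)  # 1.0 - 1.5 floored
  signed <- baseline_corrected_rms(f$trial, f$rec, floor_at_zero = FALSE)
  expect_equal(signed[2], -0.5, tolerance = 1e-9)
})

test_that("windows overlapping the edge-trim margin are rejected", {
  f <- make_two_window_recording(c(1, 1), c(1, 1))
  bad <- task_trial("index", "high", "dynamic",
                    active_window = c(1, 2000), rest_window = c(3000, 4000))
  expect_error(baseline_corrected_rms(bad, f$rec), "outside the usable")
})

test_that("average_repetitions is the elementwise mean", {
  v <- c(1, 2, 3)
  expect_equal(average_repetitions(list(v, v, v)), v)
  expect_equal(average_repetitions(list(0 * v, v)), v / 2)
  set.seed(5)
  reps <- replicate(3, rnorm(63), simplify = FALSE)
  manual <- numeric(63)
  for (i in 1:63) manual[i] <- (reps[[1]][i] + reps[[2]][i] + reps[[3]][i]) / 3
  expect_equal(average_repetitions(reps), manual)
  expect_error(average_repetitions(list(1:3, 1:4)), "mismatched")
})

test_that("average_repetitions commutes with channel permutation", {
  set.seed(6)
  reps <- replicate(3, rnorm(20), simplify = FALSE)
  p <- sample(20)
  lhs <- average_repetitions(lapply(reps, function(r) r[p]))
  rhs <- average_repetitions(reps)[p]
  expect_equal(lhs, rhs)
})

test_that("mean_grid_rms averages across channels", {
  expect_equal(mean_grid_rms(rep(2.5, 63)), 2.5)
  expect_equal(mean_grid_rms(c(63, rep(0, 62))), 1)
  set.seed(8)
  x <- runif(63)
  expect_equal(mean_grid_rms(x), sum(x) / 63)
})

test_that("normalize_subject_effort divides by the reference condition", {
  tab <- expand.grid(finger = c("index", "four"), effort = c("high", "low"),
                     stringsAsFactors = FALSE)
  tab$mean_rms <- c(2, 4, 1, 2)
  out <- normalize_subject_effort(tab)
  expect_equal(out$norm_rms[out$finger == "four" & out$effort == "high"], 1)
  expect_equal(out$norm_rms[out$finger == "index" & out$effort == "high"],
               0.5)
  expect_equal(out$norm_rms, tab$mean_rms / 4)
  # when the reference is the maximum everything is in [0, 1]
  expect_true(all(out$norm_rms <= 1 & out$norm_rms >= 0))
  expect_error(normalize_subject_effort(tab[tab$finger == "index", ]),
               "reference condition")
  tab0 <- tab; tab0$mean_rms[tab0$finger == "four" &
                             tab0$effort == "high"] <- 0
  expect_error(normalize_subject_effort(tab0), "positive")
})

test_that("recording round-trips through its file format", {
  g <- build_grid(2, 3)
  set.seed(10)
  sig <- matrix(rnorm(6 * 100), 6)
  tr <- task_trial("ring", "low", "static", c(41, 80), c(1, 30),
                   repetition = 2)
  rec <- emg_recording(sig, 2000, trials = list(tr), grid = g,
                       meta = list(seed = 123L, note = "fixture"))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  # metadata bit-exact
  expect_identical(back$fs, rec$fs)
  expect_identical(back$trials[[1]]$finger, "ring")
  expect_identical(back$trials[[1]]$active_window, c(41L, 80L))
  expect_identical(back$trials[[1]]$rest_window, c(1L, 30L))
  expect_identical(back$trials[[1]]$repetition, 2L)
  expect_equal(back$meta$seed, 123L)
  expect_identical(back$meta$note, "fixture")
  expect_equal(back$grid$x_percent, g$x_percent)
  # numeric within text formatting precision
  expect_equal(back$signal, rec$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rest-only recordings give identically zero corrected RMS", {
  cfg <- single_compartment_config(noise_rms = 0.3, seed = 21)
  # all gains zero: pure baseline noise everywhere
  cfg$compartments$index$gain <- 1e-300
  sim <- simulate_recording(cfg, "index", "high", "static")
  rec <- emg_bandpass(sim$recording)
  rms <- condition_rms(rec)
  # active and rest windows are then exchangeable; flooring keeps ~half at
  # exactly 0 and the rest at sampling-noise level
  expect_lt(max(rms), 0.02)
})
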