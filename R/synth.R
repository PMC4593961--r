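# Synthetic compartmentalized surface-EMG generator.
#
# Each finger's muscle compartment is a 2-D Gaussian amplitude territory on
# the relative-coordinate grid plane.  Channel signals are band-limited
# (20-400 Hz) Gaussian-process carriers scaled so that the active-window
# RMS equals the configured compartment amplitude, with an always-on
# additive baseline-noise carrier.  Carriers are independent across
# channels, and independent amplitude contributions combine
# root-sum-of-squares (independent sources add in power).  The generator
# emits full ground truth (noise-free RMS map, exact centroid, parameters)
# so every pipeline stage can be tested against known values.

#' Muscle-compartment territory model
#'
#' @param finger Compartment label (`"index"`, `"middle"`, `"ring"`,
#'   `"little"`).
#' @param center Length-2 numeric `(x, y)` territory center in percent
#'   (circumference, length).
#' @param spread Length-2 positive numeric `(sd_x, sd_y)` of the Gaussian
#'   amplitude profile, in percent.
#' @param gain Positive peak RMS amplitude (arbitrary units).
#' @return Object of class `compartment_model`.
#' @export
compartment <- function(finger, center, spread, gain = 1) {
  stopifnot(length(center) == 2, length(spread) == 2, all(spread > 0),
            gain > 0)
  structure(list(finger = finger, center = as.numeric(center),
                 spread = as.numeric(spread), gain = as.numeric(gain)),
            class = "compartment_model")
}

#' Default compartment layout of the finger extensor
#'
#' Encodes the qualitative anatomical geography of the extensor digitorum
#' communis compartments: the index-finger territory most distal
#' (~60% forearm length), the middle-finger territory most proximal
#' (~30%), and the ring and little territories in between (~40--50%) and
#' mutually close.  Circumferential centers sit on the extensor side of
#' the forearm (x near 55--65%), with the middle compartment slightly more
#' ulnar.  All values are overridable.
#'
#' @return Named list of four [compartment()] objects.
#' @export
default_compartments <- function() {
  list(
    index  = compartment("index",  center = c(58, 60), spread = c(12, 10)),
    middle = compartment("middle", center = c(66, 30), spread = c(12, 10)),
    ring   = compartment("ring",   center = c(55, 44), spread = c(12, 10)),
    little = compartment("little", center = c(61, 50), spread = c(12, 10))
  )
}

#' Default enslaving matrix
#'
#' Activation fraction of each finger compartment (columns) for each
#' instructed task (rows: the four single-finger tasks plus the four-finger
#' task).  The instructed finger's own compartment is 1; neighbouring
#' compartments receive low-level co-activation (enslaving); the
#' four-finger row is all ones.  Levels are order-of-magnitude choices
#' (no quantitative enslaving levels are established for this muscle);
#' adjacent fingers get 0.15, non-adjacent 0.05.
#'
#' @return 5 x 4 numeric matrix with dimnames
#'   (`task` in index/middle/ring/little/four, `compartment`).
#' @export
default_enslaving <- function() {
  fingers <- c("index", "middle", "ring", "little")
  m <- rbind(
    index  = c(1.00, 0.15, 0.05, 0.05),
    middle = c(0.15, 1.00, 0.15, 0.05),
    ring   = c(0.05, 0.15, 1.00, 0.15),
    little = c(0.05, 0.05, 0.15, 1.00),
    four   = c(1.00, 1.00, 1.00, 1.00)
  )
  colnames(m) <- fingers
  m
}

#' Simulation configuration
#'
#' Bundles everything needed to synthesize one subject's recordings: grid,
#' compartment territories, enslaving matrix, effort gains, the territory
#' displacement applied in dynamic-constraint trials, baseline noise
#' amplitude, the trial protocol, sampling rate and seed.
#'
#' Defaults encode the standard protocol (3 repetitions of 5-s contraction
#' with 4-s rests, 2 kHz sampling) and a low-effort gain of 0.5 (half the
#' high-effort drive).  `noise_rms` is expressed on the same arbitrary
#' amplitude scale as the compartment gains (default 0.05, i.e. 5% of a
#' unit-gain compartment peak).
#'
#' @param grid An [build_grid()] electrode grid (default the 7 x 9
#'   full-forearm grid).
#' @param compartments Named list of [compartment()] models (default
#'   [default_compartments()]).
#' @param enslaving Task-by-compartment activation-fraction matrix
#'   (default [default_enslaving()]).
#' @param effort_gain Named list with `high` and `low` multiplicative
#'   drives, `0 < low < high`.
#' @param dynamic_shift Length-2 `(dx, dy)` percent displacement added to
#'   every compartment center in dynamic-constraint trials (default
#'   `c(0, -3)`: a 3% shift toward the proximal end, emulating muscle-belly
#'   shortening when the finger moves freely).
#' @param noise_rms Baseline-noise RMS present in rest and active windows.
#' @param n_repetitions Number of contraction repetitions per condition.
#' @param active_s,rest_s Contraction and rest durations in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(grid = build_grid(7, 9),
                              compartments = default_compartments(),
                              enslaving = default_enslaving(),
                              effort_gain = list(high = 1.0, low = 0.5),
                              dynamic_shift = c(0, -3),
                              noise_rms = 0.05,
                              n_repetitions = 3L,
                              active_s = 5, rest_s = 4,
                              fs = 2000, seed = 20151006L) {
  stopifnot(inherits(grid, "electrode_grid"),
            effort_gain$high > 0, effort_gain$low > 0,
            noise_rms >= 0, n_repetitions >= 1, active_s > 0, rest_s > 0,
            fs > 0, length(dynamic_shift) == 2)
  stopifnot(is.matrix(enslaving),
            nrow(enslaving) == length(compartments) + 1,
            ncol(enslaving) == length(compartments))
  structure(
    list(grid = grid, compartments = compartments, enslaving = enslaving,
         effort_gain = effort_gain, dynamic_shift = as.numeric(dynamic_shift),
         noise_rms = noise_rms, n_repetitions = as.integer(n_repetitions),
         active_s = active_s, rest_s = rest_s, fs = fs,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Per-channel spatial weights of one compartment
#'
#' `w(ch) = gain * exp(-(x - cx)^2 / (2 sd_x^2) - (y - cy)^2 / (2 sd_y^2))`
#' evaluated at every electrode's relative coordinates.
#'
#' @param comp A [compartment()].
#' @param grid An [build_grid()] grid.
#' @param shift Optional `(dx, dy)` percent displacement of the center.
#' @return Non-negative numeric vector, one weight per channel.
#' @export
spatial_weights <- function(comp, grid, shift = c(0, 0)) {
  stopifnot(inherits(comp, "compartment_model"),
            inherits(grid, "electrode_grid"))
  cx <- comp$center[1] + shift[1]
  cy <- comp$center[2] + shift[2]
  ch <- grid$channels
  comp$gain * exp(-(ch$x - cx)^2 / (2 * comp$spread[1]^2) -
                  (ch$y - cy)^2 / (2 * comp$spread[2]^2))
}

# small deterministic string hash (FNV-1a, folded to a positive 31-bit int)
str_seed <- function(...) {
  s <- paste(..., collapse = "|")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# unit-RMS band-limited Gaussian carrier of length n; an optional inner
# shaping filter concentrates power mid-band (the typical surface-EMG
# spectrum peaks near 60-150 Hz), keeping the carrier essentially
# transparent to the 20-400 Hz analysis filter
band_limited_carrier <- function(n, coef, shaping = NULL) {
  x <- stats::rnorm(n)
  if (!is.null(shaping)) x <- filtfilt_signal(shaping, x)
  x <- filtfilt_signal(coef, x)
  x / sqrt(mean(x^2))
}

#' Noise-free per-channel activation RMS for one condition
#'
#' The deterministic amplitude model: per channel,
#' `sqrt(sum_c (effort_gain * enslaving[task, c] * w_c)^2)` over
#' compartments `c`, with the dynamic-constraint center shift applied when
#' `constraint == "dynamic"`.
#'
#' @param config A [simulation_config()].
#' @param finger,effort,constraint Condition labels.
#' @return Numeric per-channel vector of true activation RMS.
#' @export
true_activation_rms <- function(config, finger, effort, constraint) {
  stopifnot(inherits(config, "simulation_config"))
  finger <- match.arg(finger, rownames(config$enslaving))
  effort <- match.arg(effort, names(config$effort_gain))
  constraint <- match.arg(constraint, c("dynamic", "static"))
  shift <- if (constraint == "dynamic") config$dynamic_shift else c(0, 0)
  g <- config$effort_gain[[effort]]
  contrib2 <- 0
  for (cname in colnames(config$enslaving)) {
    w <- spatial_weights(config$compartments[[cname]], config$grid,
                         shift = shift)
    contrib2 <- contrib2 + (g * config$enslaving[finger, cname] * w)^2
  }
  sqrt(contrib2)
}

#' Simulate one annotated recording for one condition
#'
#' Generates the full protocol for a single condition: `n_repetitions`
#' blocks of (`rest_s` seconds rest, `active_s` seconds contraction).
#' During contraction each channel carries an independent band-limited
#' (20--400 Hz) Gaussian carrier -- spectrally concentrated mid-band
#' (60--250 Hz shaping), like real surface EMG -- with RMS equal to the
#' condition's true activation amplitude on that channel, on top of an
#' always-on broadband (20--400 Hz) baseline noise carrier of RMS
#' `noise_rms`.  Rest windows contain baseline noise
#' only.  Trial annotations pair each contraction with the 2-s rest window
#' ending 0.25 s before contraction onset.  Deterministic given
#' `config$seed` (plus the condition and `subject` labels).
#'
#' @inheritParams true_activation_rms
#' @param subject Integer label mixed into the RNG stream so cohort
#'   subjects get independent realizations.
#' @return List with `recording` (an [emg_recording()]) and `truth`
#'   (list: `rms` per-channel noise-free activation, `map`, `centroid`,
#'   `condition`, `config` parameters echo).
#' @export
simulate_recording <- function(config, finger, effort, constraint,
                               subject = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs
  n_act <- round(config$active_s * fs)
  n_rest <- round(config$rest_s * fs)
  n_rep <- config$n_repetitions
  # 0.5 s tail after the last contraction keeps its analysis window clear
  # of the filter edge-trim margin
  n_tail <- round(0.5 * fs)
  n_tot <- n_rep * (n_rest + n_act) + n_tail
  true_rms <- true_activation_rms(config, finger, effort, constraint)
  n_ch <- length(true_rms)

  coef <- butter_bandpass(20, 400, fs, 2)
  shaping <- butter_bandpass(60, 250, fs, 2)
  env <- numeric(n_tot)
  trials <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    a0 <- (r - 1) * (n_rest + n_act) + n_rest + 1
    a1 <- a0 + n_act - 1
    env[a0:a1] <- 1
    rest_end <- a0 - 1 - round(0.25 * fs)
    trials[[r]] <- task_trial(finger, effort, constraint,
                              active_window = c(a0, a1),
                              rest_window = c(rest_end - 2 * fs + 1, rest_end),
                              repetition = r)
  }

  set.seed(str_seed(config$seed, subject, finger, effort, constraint))
  sig <- matrix(0, n_ch, n_tot)
  for (ch in seq_len(n_ch)) {
    noise <- band_limited_carrier(n_tot, coef) * config$noise_rms
    if (true_rms[ch] > 0) {
      act <- band_limited_carrier(n_tot, coef, shaping) * true_rms[ch] * env
      sig[ch, ] <- act + noise
    } else {
      sig[ch, ] <- noise
    }
  }

  truth_map <- build_map(true_rms, config$grid,
                         condition = paste(finger, effort, constraint,
                                           sep = "_"))
  truth <- list(
    rms = true_rms,
    map = truth_map,
    centroid = if (sum(true_rms) > 0) map_centroid(truth_map) else
      c(cx = NA_real_, cy = NA_real_),
    condition = list(finger = finger, effort = effort,
                     constraint = constraint),
    noise_rms = config$noise_rms, seed = config$seed, subject = subject
  )
  rec <- emg_recording(sig, fs = fs, trials = trials, grid = config$grid,
                       meta = list(seed = config$seed, subject = subject,
                                   condition = truth$condition,
                                   synthetic = TRUE))
  list(recording = rec, truth = truth)
}

#' The full task design
#'
#' @return Data frame of the 20 conditions: 5 fingers x 2 efforts x
#'   2 constraints.
#' @export
task_design <- function() {
  expand.grid(finger = c("index", "middle", "ring", "little", "four"),
              effort = c("high", "low"),
              constraint = c("dynamic", "static"),
              stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort (lazy)
#'
#' Draws per-subject parameter jitter -- Gaussian perturbation of
#' compartment centers, multiplicative log-normal-like jitter of gains, and
#' additive jitter of off-diagonal enslaving entries (clamped to be
#' non-negative; instructed-finger entries stay 1) -- and returns a cohort
#' object holding one fully-specified [simulation_config()] per subject.
#' Recordings are *not* materialized (a full cohort is several gigabytes of
#' signal); realize them on demand with [cohort_recording()] or stream the
#' whole analysis with [analyze_cohort()].
#'
#' @param config Template [simulation_config()].
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer cohort seed (defaults to `config$seed`).
#' @param jitter Named list: `center_sd` (percent, default 2),
#'   `gain_sd` (relative, default 0.1), `enslaving_sd` (absolute, default
#'   0.03).  Set all to 0 for identical subjects.
#' @return Object of class `emg_cohort`: list with `subject_configs`,
#'   `design` ([task_design()]), `seed`, `jitter`, `template`.
#' @export
generate_cohort <- function(config, n_subjects = 10L, seed = config$seed,
                            jitter = list(center_sd = 2, gain_sd = 0.1,
                                          enslaving_sd = 0.03)) {
  stopifnot(inherits(config, "simulation_config"), n_subjects >= 1)
  set.seed(str_seed(seed, "cohort-jitter"))
  subject_configs <- lapply(seq_len(n_subjects), function(s) {
    cfg <- config
    cfg$seed <- as.integer((seed + s) %% 2147483647)
    cfg$compartments <- lapply(cfg$compartments, function(cp) {
      cp$center <- cp$center + stats::rnorm(2, 0, jitter$center_sd)
      cp$gain <- cp$gain * exp(stats::rnorm(1, 0, jitter$gain_sd))
      cp
    })
    ens <- cfg$enslaving
    offdiag <- ens != 1
    ens[offdiag] <- pmax(0, ens[offdiag] +
                           stats::rnorm(sum(offdiag), 0,
                                        jitter$enslaving_sd))
    cfg$enslaving <- ens
    cfg
  })
  structure(list(subject_configs = subject_configs, design = task_design(),
                 seed = as.integer(seed), jitter = jitter,
                 template = config),
            class = "emg_cohort")
}

#' Realize one cohort recording
#'
#' @param cohort An [generate_cohort()] object.
#' @param subject Subject index.
#' @param finger,effort,constraint Condition labels.
#' @return As [simulate_recording()].
#' @export
cohort_recording <- function(cohort, subject, finger, effort, constraint) {
  stopifnot(inherits(cohort, "emg_cohort"))
  simulate_recording(cohort$subject_configs[[subject]], finger, effort,
                     constraint, subject = subject)
}

#' Run the full pipeline over a cohort (streaming)
#'
#' For every subject and condition: simulate the recording, band-pass
#' filter, compute baseline-corrected per-channel RMS averaged over
#' repetitions, and build the activation map.  Recordings are discarded as
#' soon as their map is computed, so memory stays flat.
#'
#' @param cohort An [generate_cohort()] cohort.
#' @param conditions Optional subset of the design (data frame with
#'   `finger`, `effort`, `constraint`); default the full 20-condition
#'   design.
#' @param floor_at_zero Passed to [baseline_corrected_rms()].
#' @param verbose Print one line per subject.
#' @return List with `maps` (nested list `maps[[subject]][[condition_id]]`
#'   of `rms_map`s, condition_id `finger_effort_constraint`), `summary`
#'   (tidy data frame: subject, finger, effort, constraint, mean_rms, cx,
#'   cy), and `truth` (same shape, from the generator's ground truth).
#' @export
analyze_cohort <- function(cohort, conditions = NULL, floor_at_zero = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "emg_cohort"))
  if (is.null(conditions)) conditions <- cohort$design
  n_subj <- length(cohort$subject_configs)
  maps <- vector("list", n_subj)
  rows <- list()
  truth_rows <- list()
  for (s in seq_len(n_subj)) {
    if (verbose) message("subject ", s, "/", n_subj)
    maps[[s]] <- list()
    for (i in seq_len(nrow(conditions))) {
      cnd <- conditions[i, ]
      sim <- cohort_recording(cohort, s, cnd$finger, cnd$effort,
                              cnd$constraint)
      rec <- emg_bandpass(sim$recording)
      rms <- condition_rms(rec, floor_at_zero = floor_at_zero)
      cid <- paste(cnd$finger, cnd$effort, cnd$constraint, sep = "_")
      m <- build_map(rms, cohort$subject_configs[[s]]$grid, condition = cid)
      maps[[s]][[cid]] <- m
      cen <- if (sum(m$values) > 0) map_centroid(m) else
        c(cx = NA_real_, cy = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, finger = cnd$finger, effort = cnd$effort,
        constraint = cnd$constraint, mean_rms = mean_grid_rms(rms),
        cx = cen[["cx"]], cy = cen[["cy"]], stringsAsFactors = FALSE)
      tc <- sim$truth$centroid
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject = s, finger = cnd$finger, effort = cnd$effort,
        constraint = cnd$constraint,
        mean_rms = mean(sim$truth$rms),
        cx = tc[["cx"]], cy = tc[["cy"]], stringsAsFactors = FALSE)
    }
  }
  list(maps = maps, summary = do.call(rbind, rows),
       truth = do.call(rbind, truth_rows))
}
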