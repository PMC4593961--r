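# Shared fixtures.  The default-cohort analysis is expensive (10 subjects
# x 20 conditions of full-length signal), so it is computed lazily once
# per test session and reused by every test that needs it.

.fixtures <- new.env(parent = emptyenv())

default_cohort_results <- function() {
  if (is.null(.fixtures$cohort_res)) {
    cohort <- generate_cohort(simulation_config(), n_subjects = 10)
    .fixtures$cohort_res <- analyze_cohort(cohort)
  }
  .fixtures$cohort_res
}

# single-compartment simulation config (one territory, no enslaving):
# task rows are "index" (the compartment itself) and "four"
single_compartment_config <- function(noise_rms = 0, seed = 11L,
                                      center = c(55, 60),
                                      spread = c(12, 10)) {
  ens <- matrix(1, nrow = 2, ncol = 1,
                dimnames = list(c("index", "four"), "index"))
  simulation_config(
    compartments = list(index = compartment("index", center, spread)),
    enslaving = ens, noise_rms = noise_rms, seed = seed
  )
}

random_map <- function(grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_map(runif(n_channels(grid)), grid)
}

# brute-force double-loop centroid, written directly from the definition
centroid_bruteforce <- function(map) {
  v <- map$values
  xs <- map$grid$x_percent
  ys <- map$grid$y_percent
  num_x <- 0; num_y <- 0; den <- 0
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      num_x <- num_x + v[i, j] * xs[j]
      num_y <- num_y + v[i, j] * ys[i]
      den <- den + v[i, j]
    }
  }
  c(cx = num_x / den, cy = num_y / den)
}

# independent repeated-measures ANOVA oracle built on base R's
# multivariate linear model machinery (anova.mlm + mauchly.test)
rm_anova_oracle <- function(tab, factors, response = "response",
                            subject = "subject") {
  lv <- lapply(factors, function(f) levels(factor(tab[[f]])))
  names(lv) <- factors
  cells <- expand.grid(lv, stringsAsFactors = FALSE)
  key_tab <- do.call(paste, c(lapply(factors, function(f)
    as.character(tab[[f]])), sep = "\r"))
  key_cells <- do.call(paste, c(cells, sep = "\r"))
  sid <- factor(tab[[subject]])
  Y <- matrix(NA_real_, nlevels(sid), nrow(cells))
  Y[cbind(as.integer(sid), match(key_tab, key_cells))] <- tab[[response]]
  idata <- as.data.frame(lapply(cells, factor))
  fit <- stats::lm(Y ~ 1)
  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    M <- stats::as.formula(paste("~", paste(eff, collapse = "*")))
    X <- switch(as.character(length(eff)),
                "1" = ~1,
                "2" = stats::as.formula(paste("~", paste(eff,
                                                         collapse = "+"))),
                "3" = stats::as.formula(paste("~(", paste(eff,
                                                          collapse = "+"),
                                              ")^2")))
    a <- stats::anova(fit, M = M, X = X, idata = idata, test = "Spherical")
    mt <- tryCatch(
      stats::mauchly.test(fit, M = M, X = X, idata = idata),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    # stats are on the "(Intercept)" row of the anova.mlm table
    data.frame(effect = paste(eff, collapse = ":"),
               F = a["(Intercept)", "F"],
               df1 = a["(Intercept)", "num Df"],
               df2 = a["(Intercept)", "den Df"],
               p = a["(Intercept)", "Pr(>F)"],
               p_gg = a["(Intercept)", "G-G Pr"],
               mauchly_W = unname(unlist(mt$statistic)[1]),
               mauchly_p = unname(mt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a simulated balanced within-subject table
simulate_scc_table <- function(n_subj = 10, seed = 42, effect_finger = 0) {
  set.seed(seed)
  tab <- expand.grid(subject = factor(seq_len(n_subj)),
                     finger = c("index", "middle", "ring", "little", "four"),
                     effort = c("high", "low"),
                     constraint = c("dynamic", "static"),
                     stringsAsFactors = FALSE)
  tab$response <- stats::rnorm(nrow(tab)) +
    effect_finger * as.numeric(factor(tab$finger)) +
    stats::rnorm(n_subj)[as.integer(tab$subject)]
  tab
}
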