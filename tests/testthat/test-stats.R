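test_that("rm_anova matches the independent multivariate-model oracle", {
  tab <- simulate_scc_table(n_subj = 10, seed = 42, effect_finger = 0.8)
  mine <- rm_anova(tab, c("finger", "effort", "constraint"))
  orac <- rm_anova_oracle(tab, c("finger", "effort", "constraint"))
  expect_equal(mine$effect, orac$effect)
  expect_equal(mine$F, orac$F, tolerance = 1e-8)
  expect_equal(mine$p_uncorrected, orac$p, tolerance = 1e-8)
  # Greenhouse-Geisser p and Mauchly agree wherever sphericity is testable
  multi <- !is.na(mine$mauchly_p)
  expect_equal(mine$mauchly_W[multi], orac$mauchly_W[multi],
               tolerance = 1e-8)
  # base R's second-order Box term uses the raw cell count where the
  # published formula uses the contrast dimension; agreement is therefore
  # to the first-order approximation only
  expect_equal(mine$mauchly_p[multi], orac$mauchly_p[multi],
               tolerance = 5e-3)
  gg_mine <- stats::pf(mine$F, mine$epsilon * c(4, 1, 1, 4, 4, 1, 4),
                       mine$epsilon * 9 * c(4, 1, 1, 4, 4, 1, 4),
                       lower.tail = FALSE)
  expect_equal(gg_mine, orac$p_gg, tolerance = 1e-8)
})

test_that("two-level factors have epsilon exactly 1, no correction", {
  tab <- simulate_scc_table(n_subj = 8, seed = 7)
  res <- rm_anova(tab, c("effort", "constraint"))
  expect_equal(res$epsilon, rep(1, 3))
  expect_true(all(!res$corrected))
  expect_true(all(is.na(res$mauchly_p)))
})

test_that("constant response gives F = 0 for every effect", {
  tab <- simulate_scc_table(n_subj = 6, seed = 1)
  tab$response <- 5
  res <- rm_anova(tab, c("finger", "effort"))
  expect_equal(res$F, rep(0, 3))
})

test_that("effects are invariant to level relabeling and response shifts", {
  tab <- simulate_scc_table(n_subj = 8, seed = 30, effect_finger = 0.5)
  base <- rm_anova(tab, c("finger", "effort"))
  shifted <- tab; shifted$response <- shifted$response + 100
  expect_equal(rm_anova(shifted, c("finger", "effort"))$F, base$F)
  relab <- tab
  relab$finger <- c(index = "D1", middle = "D2", ring = "D3",
                    little = "D4", four = "ALL")[relab$finger]
  expect_equal(rm_anova(relab, c("finger", "effort"))$F, base$F)
})

test_that("degenerate designs are rejected", {
  tab <- simulate_scc_table(n_subj = 4, seed = 2)
  expect_error(rm_anova(tab[-1, ], c("finger", "effort", "constraint")),
               "balanced")
  one <- tab[tab$subject == "1", ]
  expect_error(rm_anova(one, c("finger", "effort")), "2 subjects")
  expect_error(rm_anova(tab, character(0)), "1 to 3")
})

test_that("tukey_pairwise with two levels equals the paired comparison", {
  tab <- simulate_scc_table(n_subj = 10, seed = 77)
  tk <- tukey_pairwise(tab, "effort")
  expect_equal(nrow(tk), 1L)
  # paired t on subject means
  a <- tapply(tab$response[tab$effort == "high"],
              tab$subject[tab$effort == "high"], mean)
  b <- tapply(tab$response[tab$effort == "low"],
              tab$subject[tab$effort == "low"], mean)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(tk$diff, unname(tt$estimate), tolerance = 1e-12)
})

test_that("tukey_pairwise flags exactly the shifted level's comparisons", {
  set.seed(90)
  n <- 10
  tab <- expand.grid(subject = factor(1:n),
                     finger = c("index", "middle", "ring", "little", "four"),
                     stringsAsFactors = FALSE)
  subj_eff <- rnorm(n, sd = 0.3)
  tab$response <- rnorm(nrow(tab), sd = 0.5) +
    subj_eff[as.integer(tab$subject)] +
    ifelse(tab$finger == "middle", 2.5, 0)
  tk <- tukey_pairwise(tab, "finger")
  hit <- tk$p_adj < 0.05
  involves_middle <- tk$level_a == "middle" | tk$level_b == "middle"
  expect_equal(hit, involves_middle)

  # permutation-based family-wise oracle: permute level labels within
  # subject, max-q reference distribution
  cellm <- tapply(tab$response, list(factor(tab$subject),
                                     factor(tab$finger)), mean)
  l <- ncol(cellm)
  obs_q <- function(m) {
    lev <- colMeans(m)
    res <- m - outer(rowMeans(m), rep(1, l)) -
      outer(rep(1, nrow(m)), lev) + mean(m)
    mse <- sum(res^2) / ((l - 1) * (nrow(m) - 1))
    abs(outer(lev, lev, "-")) / sqrt(mse / nrow(m))
  }
  qs <- obs_q(cellm)
  set.seed(91)
  n_perm <- 10000
  max_q <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- t(apply(cellm, 1, sample))
    max_q[p] <- max(obs_q(perm))
  }
  p_perm <- outer(1:l, 1:l, Vectorize(function(i, j)
    mean(max_q >= qs[i, j])))
  dimnames(p_perm) <- dimnames(qs)
  for (k in seq_len(nrow(tk))) {
    pp <- p_perm[tk$level_a[k], tk$level_b[k]]
    # same significance decisions at alpha = .05, within Monte-Carlo error
    if (tk$p_adj[k] < 0.03 || tk$p_adj[k] > 0.07) {
      expect_equal(pp < 0.05, tk$p_adj[k] < 0.05)
    }
    # and numerically comparable adjusted p-values
    expect_lt(abs(pp - tk$p_adj[k]), 0.05)
  }
})

test_that("exactly equal level means give adjusted p of 1", {
  # level means identical by construction, residual variance nonzero
  tab <- expand.grid(subject = factor(1:8),
                     finger = c("a", "b", "c"), stringsAsFactors = FALSE)
  sgn <- rep(c(1, -1), 4)[as.integer(tab$subject)]
  pat <- c(a = 1, b = -1, c = 0)[tab$finger]
  tab$response <- 2 + sgn * pat
  tk <- tukey_pairwise(tab, "finger")
  expect_equal(tk$diff, rep(0, 3))
  expect_equal(tk$p_adj, rep(1, 3))
  expect_error(tukey_pairwise(tab[tab$finger == "a", ], "finger"),
               "at least 2 levels")
})

test_that("cell_contrast reproduces a paired t-test between cells", {
  tab <- simulate_scc_table(n_subj = 9, seed = 55, effect_finger = 1)
  out <- cell_contrast(tab, list(finger = "index", effort = "high"),
                       list(finger = "ring", effort = "high"))
  a <- tapply(tab$response[tab$finger == "index" & tab$effort == "high"],
              tab$subject[tab$finger == "index" & tab$effort == "high"],
              mean)
  b <- tapply(tab$response[tab$finger == "ring" & tab$effort == "high"],
              tab$subject[tab$finger == "ring" & tab$effort == "high"],
              mean)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(out$p, tt$p.value, tolerance = 1e-12)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-12)
})
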