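# Repeated-measures ANOVA for balanced, fully within-subject factorial
# designs (one observation per subject x condition cell), with Mauchly's
# sphericity test and Greenhouse-Geisser df correction per effect, plus
# Tukey (studentized-range) pairwise comparisons.
#
# Each within-subject effect is tested against its own effect x subject
# interaction (the standard univariate repeated-measures error term).

check_balanced <- function(tab, factors, subject, response) {
  need <- c(subject, factors, response)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("table is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(tab[[response]])) stop("response must be numeric",
                                         call. = FALSE)
  cells <- interaction(lapply(c(subject, factors),
                              function(f) factor(tab[[f]])),
                       drop = FALSE)
  counts <- table(cells)
  if (length(unique(as.integer(counts))) != 1L || any(counts < 1)) {
    stop("design must be balanced and complete: the same number of ",
         "observations in every subject x condition cell", call. = FALSE)
  }
  invisible(TRUE)
}

# collapse replicate observations (e.g. over factors not in the design)
# to one cell mean per subject x condition
aggregate_cells <- function(tab, factors, subject, response) {
  by <- c(subject, factors)
  agg <- stats::aggregate(tab[[response]],
                          lapply(by, function(f) tab[[f]]), mean)
  names(agg) <- c(by, response)
  agg
}

# marginal mean of the response over each level combination of `by`
marg_means <- function(tab, by, response) {
  if (length(by) == 0) return(mean(tab[[response]]))
  tapply(tab[[response]], lapply(by, function(f) factor(tab[[f]])), mean)
}

# sum of squares of a factorial term via Moebius inversion over sub-terms:
# effect(t) = sum_{u subset t} (-1)^{|t|-|u|} marginal_mean(u)
term_ss <- function(tab, term, response, n_total) {
  k <- length(term)
  grand <- mean(tab[[response]])
  eff <- marg_means(tab, term, response) * 0
  for (sz in 0:k) {
    subs <- if (sz == 0) list(character(0)) else
      utils::combn(term, sz, simplify = FALSE)
    sign <- (-1)^(k - sz)
    for (u in subs) {
      mu <- if (length(u) == 0) grand else marg_means(tab, u, response)
      if (length(u) == 0) {
        eff <- eff + sign * mu
      } else {
        # broadcast marginal means over the full term's level grid
        dn <- dimnames(eff)
        idx <- match(u, term)
        grid <- expand.grid(dn, stringsAsFactors = FALSE)
        mu_arr <- array(0, dim = dim(eff), dimnames = dn)
        key <- do.call(paste, c(grid[idx], sep = "\r"))
        mu_flat <- as.vector(mu)
        mu_names <- do.call(paste,
          c(expand.grid(dimnames(mu), stringsAsFactors = FALSE), sep = "\r"))
        mu_arr[] <- mu_flat[match(key, mu_names)]
        eff <- eff + sign * mu_arr
      }
    }
  }
  reps <- n_total / length(eff)
  sum(eff^2) * reps
}

# orthonormal contrast matrix over condition cells for one effect.
# Cells are ordered as the row order of expand.grid over factor levels.
effect_contrast <- function(levels_by_factor, effect) {
  mats <- lapply(names(levels_by_factor), function(f) {
    l <- length(levels_by_factor[[f]])
    if (f %in% effect) {
      # orthonormal (l-1)-column contrasts
      qr.Q(qr(stats::contr.helmert(l)))
    } else {
      matrix(1 / sqrt(l), nrow = l, ncol = 1)
    }
  })
  # expand.grid varies its FIRST factor fastest -> that factor is the
  # rightmost Kronecker operand
  out <- Reduce(function(a, b) kronecker(b, a), mats)
  out
}

mauchly_gg <- function(Y, C) {
  # Y: subjects x cells response matrix; C: cells x p orthonormal contrast
  Tm <- Y %*% C
  p <- ncol(Tm)
  n <- nrow(Tm)
  Tc <- sweep(Tm, 2, colMeans(Tm))
  V <- crossprod(Tc)
  trV <- sum(diag(V))
  eps <- if (p == 1) 1 else trV^2 / (p * sum(V^2))
  if (p == 1 || n - 1 <= p) {
    return(list(W = NA_real_, p_mauchly = NA_real_, epsilon = eps))
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    return(list(W = 0, p_mauchly = 0, epsilon = eps))
  }
  logW <- sum(log(ev)) - p * log(trV / p)
  # Box approximation (two-term chi-square blend), as in standard
  # treatments of Mauchly's W
  ndf <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * ndf)
  z <- -ndf * rho * logW
  f <- p * (p + 1) / 2 - 1
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * (ndf * p * rho)^2)
  pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
  list(W = exp(logW), p_mauchly = pr1 + w2 * (pr2 - pr1), epsilon = eps)
}

#' Repeated-measures ANOVA for a balanced within-subject factorial
#'
#' Univariate repeated-measures analysis of variance for a fully
#' within-subject design with 1--3 factors.  Replicate observations within
#' a subject x condition cell (e.g. over design factors not listed in
#' `factors`) are averaged first; the design must be balanced.  Every main
#' effect and interaction is tested
#' against its own effect-by-subject interaction.  For effects with more
#' than one numerator degree of freedom, Mauchly's test of sphericity is
#' run, and when it is significant (`p < sphericity_alpha`) the degrees of
#' freedom are multiplied by the Greenhouse--Geisser epsilon before
#' computing the p-value.
#'
#' @param tab Long-format data frame: one row per subject x condition cell.
#' @param factors Character vector of 1--3 within-subject factor column
#'   names.
#' @param response Name of the numeric response column (default
#'   `"response"`).
#' @param subject Name of the subject-id column (default `"subject"`).
#' @param sphericity_alpha Significance level of Mauchly's test that
#'   triggers the Greenhouse--Geisser correction (default 0.05).
#' @return Data frame of class `rm_anova`, one row per effect, with columns
#'   `effect`, `F`, `df1`, `df2`, `epsilon`, `mauchly_W`, `mauchly_p`,
#'   `corrected` (logical), `p` (corrected when `corrected`), and
#'   `p_uncorrected`.
#' @examples
#' tab <- expand.grid(subject = factor(1:8), effort = c("high", "low"),
#'                    finger = c("index", "middle", "ring"))
#' set.seed(1)
#' tab$response <- rnorm(nrow(tab)) + as.numeric(tab$finger)
#' rm_anova(tab, c("finger", "effort"))
#' @export
rm_anova <- function(tab, factors, response = "response",
                     subject = "subject", sphericity_alpha = 0.05) {
  if (length(factors) < 1 || length(factors) > 3) {
    stop("1 to 3 within-subject factors are supported", call. = FALSE)
  }
  check_balanced(tab, factors, subject, response)
  tab <- aggregate_cells(tab, factors, subject, response)
  n_subj <- length(unique(tab[[subject]]))
  if (n_subj < 2) stop("need at least 2 subjects", call. = FALSE)
  lv <- lapply(factors, function(f) levels(factor(tab[[f]])))
  names(lv) <- factors
  n_total <- nrow(tab)

  # wide response matrix: subjects x cells, cells in expand.grid order
  cell_grid <- expand.grid(lv, stringsAsFactors = FALSE)
  key_tab <- do.call(paste, c(lapply(factors, function(f)
    as.character(tab[[f]])), sep = "\r"))
  key_cells <- do.call(paste, c(cell_grid, sep = "\r"))
  sid <- factor(tab[[subject]])
  Y <- matrix(NA_real_, n_subj, nrow(cell_grid))
  Y[cbind(as.integer(sid), match(key_tab, key_cells))] <- tab[[response]]

  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    df1 <- prod(vapply(eff, function(f) length(lv[[f]]) - 1L, integer(1)))
    df2 <- df1 * (n_subj - 1)
    ss_eff <- term_ss(tab, eff, response, n_total)
    ss_err <- term_ss(tab, c(eff, subject), response, n_total)
    # a null effect is 0 even when the error SS is degenerate (constant data)
    Fv <- if (ss_eff <= 0) 0 else (ss_eff / df1) / (ss_err / df2)
    sph <- mauchly_gg(Y, effect_contrast(lv, eff))
    corrected <- df1 > 1 && is.finite(sph$p_mauchly) &&
      sph$p_mauchly < sphericity_alpha
    p_un <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, sph$epsilon * df1, sph$epsilon * df2,
                      lower.tail = FALSE)
    data.frame(
      effect = paste(eff, collapse = ":"),
      F = Fv,
      df1 = if (corrected) sph$epsilon * df1 else df1,
      df2 = if (corrected) sph$epsilon * df2 else df2,
      epsilon = sph$epsilon,
      mauchly_W = sph$W,
      mauchly_p = sph$p_mauchly,
      corrected = corrected,
      p = if (corrected) p_gg else p_un,
      p_uncorrected = p_un,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Tukey pairwise comparisons for one within-subject factor
#'
#' All-pairs comparisons of the marginal level means of `factor` (averaged
#' over subjects and any other design factors), with family-wise adjusted
#' p-values from the studentized-range distribution.  The error term is
#' the factor-by-subject interaction mean square of the design collapsed
#' to subject x factor means, with `(l - 1)(n - 1)` degrees of freedom.
#' With two levels the adjusted p-value coincides with the unadjusted
#' paired comparison.
#'
#' @inheritParams rm_anova
#' @param factor_name Name of the factor column to compare.
#' @return Data frame with columns `level_a`, `level_b`, `mean_a`,
#'   `mean_b`, `diff`, `se`, `q`, `p_adj`.
#' @export
tukey_pairwise <- function(tab, factor_name, response = "response",
                           subject = "subject") {
  stopifnot(is.data.frame(tab),
            all(c(factor_name, response, subject) %in% names(tab)))
  f <- factor(tab[[factor_name]])
  l <- nlevels(f)
  if (l < 2) stop("factor must have at least 2 levels", call. = FALSE)
  sid <- factor(tab[[subject]])
  n <- nlevels(sid)
  # collapse to subject x level means (averages over other factors)
  cellm <- tapply(tab[[response]], list(sid, f), mean)
  if (any(is.na(cellm))) {
    stop("each subject must contribute to every level of the factor",
         call. = FALSE)
  }
  lev_means <- colMeans(cellm)
  subj_means <- rowMeans(cellm)
  grand <- mean(cellm)
  resid <- cellm - outer(subj_means, rep(1, l)) -
    outer(rep(1, n), lev_means) + grand
  df_err <- (l - 1) * (n - 1)
  mse <- sum(resid^2) / df_err
  se_mean <- sqrt(mse / n)
  pairs <- utils::combn(levels(f), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    d <- lev_means[pr[1]] - lev_means[pr[2]]
    q <- abs(d) / se_mean
    data.frame(level_a = pr[1], level_b = pr[2],
               mean_a = unname(lev_means[pr[1]]),
               mean_b = unname(lev_means[pr[2]]),
               diff = unname(d), se = se_mean * sqrt(2), q = unname(q),
               p_adj = stats::ptukey(q, l, df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cell-wise contrast between two condition cells
#'
#' Generic simple-effects facility: a paired t-test between two condition
#' cells (rows selected by matching all columns of `cell_a` / `cell_b`),
#' paired within subject.  Used for follow-up contrasts across condition
#' combinations where an omnibus interaction is significant.
#'
#' @inheritParams rm_anova
#' @param cell_a,cell_b Named lists selecting the two cells, e.g.
#'   `list(finger = "ring", constraint = "static")`.
#' @return Data frame with the two cell means, their difference, `t`, `df`,
#'   and two-sided `p`.
#' @export
cell_contrast <- function(tab, cell_a, cell_b, response = "response",
                          subject = "subject") {
  pick <- function(cell) {
    sel <- rep(TRUE, nrow(tab))
    for (nm in names(cell)) sel <- sel & tab[[nm]] == cell[[nm]]
    x <- tapply(tab[[response]][sel], factor(tab[[subject]][sel]), mean)
    x
  }
  a <- pick(cell_a); b <- pick(cell_b)
  stopifnot(identical(names(a), names(b)))
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  data.frame(mean_a = mean(a), mean_b = mean(b), diff = mean(d),
             t = tstat, df = n - 1,
             p = 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE))
}
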