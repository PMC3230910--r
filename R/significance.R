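#' Ordinary one-sample t-test of a pair's residuals
#'
#' Tests whether the mean interaction residual differs from zero:
#' `t = mean / (s / sqrt(K))`, two-sided p from Student's t with `K - 1`
#' degrees of freedom.
#'
#' @param x numeric vector of residuals for one pair.
#' @return list with `t`, `p`, `df`, `degenerate` (TRUE when the sample
#'   standard deviation is zero or `K < 2`; `K < 2` gives NA statistics, a
#'   zero sd gives p = 0 for a nonzero mean and p = 1 otherwise).
#' @export
ordinary_t_test <- function(x) {
  K <- sum(is.finite(x))
  x <- x[is.finite(x)]
  if (K < 2) return(list(t = NA_real_, p = NA_real_, df = K - 1,
                         degenerate = TRUE))
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0, df = K - 1, degenerate = TRUE))
  }
  t <- m / (s / sqrt(K))
  list(t = t, p = 2 * stats::pt(-abs(t), df = K - 1), df = K - 1,
       degenerate = FALSE)
}

## Newton solve of trigamma(x) = y, y > 0 (monotone decreasing)
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (it in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-12) break
    }
    x
  }, numeric(1))
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment matching on the log sample variances under the scaled-F model of
#' the moderated t-test: the per-pair sample variance is modelled as
#' `s^2 ~ s0^2 F(d, d0)`; the prior degrees of freedom `d0` and prior
#' variance `s0^2` are obtained from the mean and variance of
#' `log s^2 - digamma(d/2) + log(d/2)` via the digamma/trigamma moment
#' equations. When the empirical dispersion of the log variances is at or
#' below its theoretical minimum the prior is degenerate: `d0 = Inf` and
#' `s0^2` is the pooled (mean) variance.
#'
#' @param s2 numeric vector of positive sample variances.
#' @param df residual degrees of freedom, scalar or vector matching `s2`.
#' @return list of class `moderation_prior` with `d0`, `s0_sq`.
#' @export
fit_moderation_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2)
    stop("value error: need at least 2 finite positive variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    # no excess dispersion: pool by the unbiased arithmetic mean (the raw
    # geometric mean of s^2 would underestimate the variance severely at
    # small df and inflate every moderated statistic)
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' Moderated t-test with a fitted variance prior
#'
#' Shrinks each pair's variance toward the prior,
#' `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`, and tests
#' `t = w / sqrt(s2_post / K)` against Student's t with `d0 + d` degrees of
#' freedom (standard normal when `d0 = Inf`). With `d0 = 0` the ordinary t
#' is recovered; with `d0 = Inf` and equal K the statistic is proportional
#' to the effect size, so their rankings coincide.
#'
#' @param w per-pair effects (mean residuals).
#' @param s2 per-pair sample variances.
#' @param df per-pair residual degrees of freedom (`K - 1`).
#' @param K per-pair replicate counts.
#' @param prior a [fit_moderation_prior()] result (or list with `d0`,
#'   `s0_sq`).
#' @return data.frame with columns `t`, `p`, `df_total`.
#' @export
moderated_t_test <- function(w, s2, df, K, prior) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 <= 0)
    stop("value error: invalid moderation prior")
  s2_post <- if (is.infinite(d0)) rep_len(s0, length(w))
             else if (d0 == 0) s2
             else (d0 * s0 + df * s2) / (d0 + df)
  t <- w / sqrt(s2_post / K)
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  data.frame(t = t, p = p, df_total = df_total)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across all tested pairs; adjusted values are
#' monotone in the raw p-values and capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("value error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-pair interaction tests
#'
#' Combines the per-pair effect (mean residual), its sample standard
#' deviation across replicate measurements, the ordinary t-test, the
#' moderated t-test under a prior fitted across all pairs, and
#' Benjamini-Hochberg adjustment of both p-value sets.
#'
#' @param est an [estimate_interactions()] result.
#' @param prior optionally a pre-fitted [fit_moderation_prior()]; fitted
#'   from the data when `NULL`.
#' @return data.frame of class `pair_test_result`: `i`, `j`, `pair`, `w`,
#'   `s`, `K`, `df`, `t_ordinary`, `p_ordinary`, `t_moderated`,
#'   `p_moderated`, `p_ordinary_adj`, `p_moderated_adj`, `degenerate`.
#'   Attribute `"prior"` carries the moderation prior used.
#' @export
pair_tests <- function(est, prior = NULL) {
  r <- est$residuals
  sp <- split(r$eps, r$pair)
  keys <- names(sp)
  w <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, stats::sd, numeric(1))
  K <- vapply(sp, length, integer(1))
  df <- K - 1L
  ord <- lapply(sp, ordinary_t_test)
  if (is.null(prior)) prior <- fit_moderation_prior(s^2, df)
  mod <- moderated_t_test(w, s^2, df, K, prior)
  ij <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.frame(
    i = ij[, 1], j = ij[, 2], pair = keys,
    w = unname(w), s = unname(s), K = unname(K), df = unname(df),
    t_ordinary = vapply(ord, `[[`, numeric(1), "t"),
    p_ordinary = vapply(ord, `[[`, numeric(1), "p"),
    t_moderated = mod$t, p_moderated = mod$p,
    degenerate = vapply(ord, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$p_ordinary_adj <- bh_adjust(out$p_ordinary)
  out$p_moderated_adj <- bh_adjust(out$p_moderated)
  attr(out, "prior") <- prior
  class(out) <- c("pair_test_result", "data.frame")
  out
}

#' Schweder-Spjotvoll p-value plot and false-null estimate
#'
#' Plots `(1 - p_i, N(p_i))`, where `N(p)` counts p-values greater than `p`.
#' If all null hypotheses were true the graph would be close to the line
#' through the origin with slope m; an upward bend indicates false nulls.
#' A straight line is fit through the graph values at `x = 0` (i.e. `N(1)`)
#' and `x = 0.5` (i.e. `N(0.5)`); the number of false null hypotheses is
#' estimated as `m` minus the line's value at `x = 1`, i.e.
#' `m - (2 N(0.5) - N(1))`, floored at zero.
#'
#' @param p numeric vector of p-values (NA dropped); needs `m >= 4`.
#' @return list with `points` (data.frame `x = 1 - p`, `y = N(p)`), `m`,
#'   `line` (intercept/slope of the two-point fit), and `n_false_null`.
#' @export
schweder_spjotvoll <- function(p) {
  p <- p[is.finite(p)]
  m <- length(p)
  if (m < 4) stop("value error: need at least 4 p-values")
  Np <- function(x) sum(p > x)
  pts <- data.frame(x = 1 - p, y = vapply(p, Np, numeric(1)))
  pts <- pts[order(pts$x), ]
  rownames(pts) <- NULL
  n1 <- Np(1)                       # graph value at x = 0
  n05 <- Np(0.5)                    # graph value at x = 0.5
  slope <- (n05 - n1) / 0.5
  est <- max(0, m - (2 * n05 - n1))
  list(points = pts, m = m, line = c(intercept = n1, slope = slope),
       n_false_null = est)
}

#' Build the pseudo-ROC benchmark reference
#'
#' Positives are the pairs with ordinary-t p-value below `alpha` on the
#' full-replication data; all other tested pairs are negatives. The
#' reference is not a ground truth, but ROC comparisons against it remain
#' informative for ranking methods as long as it is enriched for truth.
#'
#' @param tests a [pair_tests()] result on the full data.
#' @param alpha positive-call threshold (default 0.001).
#' @return list of class `benchmark_reference` with `positives`,
#'   `negatives` (pair keys) and `alpha`.
#' @export
build_benchmark_reference <- function(tests, alpha = 0.001) {
  pos <- tests$pair[!is.na(tests$p_ordinary) & tests$p_ordinary < alpha]
  neg <- setdiff(tests$pair, pos)
  if (length(pos) == 0)
    warning("benchmark reference has no positives; ROC undefined downstream")
  structure(list(positives = pos, negatives = neg, alpha = alpha),
            class = "benchmark_reference")
}

#' ROC curve of a ranking statistic against a reference
#'
#' Sweeps thresholds over the statistic; at each threshold TPR is the
#' fraction of reference positives called and FPR the fraction of reference
#' negatives called. The curve is also interpolated onto a common FPR grid
#' for vertical averaging across subsets.
#'
#' @param scores named numeric vector (names are pair keys).
#' @param reference a [build_benchmark_reference()].
#' @param higher_is_stronger `TRUE` when larger scores mean stronger
#'   evidence (effect sizes); use `FALSE` for p-values.
#' @param grid common FPR grid (default 101 points on `[0, 1]`).
#' @return list of class `roc_curve`: `fpr`, `tpr` (threshold sweep points
#'   including the (0,0) and (1,1) endpoints), `grid`, `grid_tpr`, `auc`,
#'   `constant` flag.
#' @export
pseudo_roc <- function(scores, reference, higher_is_stronger = TRUE,
                       grid = seq(0, 1, length.out = 101L)) {
  keys <- names(scores)
  lab <- keys %in% reference$positives
  use <- keys %in% c(reference$positives, reference$negatives) &
    is.finite(scores)
  scores <- scores[use]; lab <- lab[use]
  nP <- sum(lab); nN <- sum(!lab)
  if (nP < 1 || nN < 1)
    stop("value error: reference needs at least one positive and one negative")
  s <- if (higher_is_stronger) -scores else scores
  o <- order(s)
  s <- s[o]; lab <- lab[o]
  ## group tied thresholds
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(lab)[last] / nP, 1)
  fpr <- c(0, cumsum(!lab)[last] / nN, 1)
  constant <- length(last) <= 1L
  if (constant)
    warning("constant ranking statistic; single-point ROC curve")
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  grid_tpr <- stats::approx(fpr, tpr, xout = grid, method = "linear",
                            ties = max, rule = 2)$y
  structure(list(fpr = fpr, tpr = tpr, grid = grid, grid_tpr = grid_tpr,
                 auc = auc, constant = constant),
            class = "roc_curve")
}

#' Vertically average ROC curves on their common FPR grid
#'
#' @param curves list of [pseudo_roc()] curves sharing the same grid.
#' @return A `roc_curve` with the pointwise-mean TPR and its trapezoidal
#'   area.
#' @export
average_roc <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$grid
  tprs <- vapply(curves, function(cv) cv$grid_tpr, numeric(length(grid)))
  mtpr <- rowMeans(tprs)
  auc <- sum(diff(grid) * (utils::head(mtpr, -1) + utils::tail(mtpr, -1)) / 2)
  structure(list(fpr = grid, tpr = mtpr, grid = grid, grid_tpr = mtpr,
                 auc = auc, constant = FALSE, n_curves = length(curves)),
            class = "roc_curve")
}

#' Benchmark the three ranking statistics on data subsets
#'
#' Mirrors the method comparison on reduced replication: each subset (a set
#' of plates) is re-analysed self-contained — main effects refit, residuals,
#' moderation prior and tests recomputed — and the rankings by ordinary-t
#' p-value, moderated-t p-value and absolute effect size are scored against
#' the full-data reference by pseudo-ROC; curves are vertically averaged
#' across subsets.
#'
#' @param screen the full `normalized_screen`.
#' @param reference a [build_benchmark_reference()] from the full data.
#' @param subsets list of character vectors of plate ids; each defines one
#'   subset/curve.
#' @param grouping replicate grouping used when refitting each subset
#'   (`"pooled"` for single-plate subsets, `"biological"` for cross-replicate
#'   subsets).
#' @return list with per-ranking average `roc_curve`s (`ordinary`,
#'   `moderated`, `effect`), the per-subset curves, and the average areas.
#' @export
benchmark_roc <- function(screen, reference, subsets, grouping = "pooled") {
  per <- list(ordinary = list(), moderated = list(), effect = list())
  for (si in seq_along(subsets)) {
    sub <- subset_plates(screen, subsets[[si]])
    fit <- fit_main_effects(sub, grouping = grouping)
    est <- estimate_interactions(sub, fit)
    tt <- pair_tests(est)
    key <- tt$pair
    per$ordinary[[si]] <- pseudo_roc(stats::setNames(tt$p_ordinary, key),
                                     reference, higher_is_stronger = FALSE)
    per$moderated[[si]] <- pseudo_roc(stats::setNames(tt$p_moderated, key),
                                      reference, higher_is_stronger = FALSE)
    per$effect[[si]] <- pseudo_roc(stats::setNames(abs(tt$w), key),
                                   reference, higher_is_stronger = TRUE)
  }
  avg <- lapply(per, average_roc)
  list(ordinary = avg$ordinary, moderated = avg$moderated,
       effect = avg$effect, per_subset = per,
       auc = vapply(avg, `[[`, numeric(1), "auc"))
}
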