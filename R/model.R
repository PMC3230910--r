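#' Robust-fitting options for the main-effect model
#'
#' @param loss `"squared"` (ordinary least squares, default), `"absolute"`
#'   (L1, via iteratively reweighted least squares), `"huber"` (M-estimation
#'   with tuning constant `huber_c`), or `"lts"` (least trimmed squares on
#'   the per-pair-per-group mean residuals, retaining `lts_fraction`).
#' @param huber_c Huber tuning constant; 1.345 gives 95% efficiency at the
#'   Gaussian model.
#' @param lts_fraction fraction of pair-group cells retained by LTS, in
#'   `[0.5, 1]`.
#' @param max_iter,tol IRLS iteration cap and parameter-change convergence
#'   tolerance.
#' @return A list of class `robust_options`.
#' @export
robust_options <- function(loss = c("squared", "absolute", "huber", "lts"),
                           huber_c = 1.345, lts_fraction = 0.75,
                           max_iter = 200L, tol = 1e-8) {
  loss <- match.arg(loss)
  if (huber_c <= 0) stop("option error: huber_c must be positive")
  if (lts_fraction < 0.5 || lts_fraction > 1)
    stop("option error: lts_fraction must be in [0.5, 1]")
  structure(list(loss = loss, huber_c = huber_c,
                 lts_fraction = lts_fraction,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "robust_options")
}

#' Number of free model parameters
#'
#' One baseline plus N main effects per replicate group, minus one
#' sum-to-zero constraint per group: `K (N + 1) - K`.
#'
#' @param N number of scored reagents (>= 2).
#' @param K number of replicate groups (>= 1).
#' @return Integer parameter count.
#' @export
count_parameters <- function(N, K) {
  if (N < 2 || K < 1) stop("value error: need N >= 2, K >= 1")
  as.integer(K * (N + 1) - K)
}

replicate_group <- function(screen, grouping) {
  w <- screen$wells
  switch(grouping,
         pooled = factor(rep("all", nrow(w))),
         biological = factor(w$bio_rep),
         technical = factor(paste(w$bio_rep, w$tech_rep, sep = ".")),
         stop("option error: unknown grouping '", grouping, "'"))
}

## one weighted LS solve of y ~ baseline + m_i + m_j, sum(m) = 0,
## via the sum contrast reparameterisation m = C theta
solve_group <- function(y, ri, rj, N, weights = NULL) {
  n <- length(y)
  A <- matrix(0, n, N)
  A[cbind(seq_len(n), ri)] <- 1
  A[cbind(seq_len(n), rj)] <- A[cbind(seq_len(n), rj)] + 1
  C <- rbind(diag(N - 1L), -1)
  X <- cbind(1, A %*% C)
  fit <- if (is.null(weights)) stats::lm.fit(X, y)
         else stats::lm.wfit(X, y, w = weights)
  if (fit$rank < ncol(X))
    stop("rank-deficiency error: main-effect model not identifiable ",
         "in this replicate group")
  beta <- fit$coefficients
  list(y0 = beta[1], m = as.numeric(C %*% beta[-1]))
}

#' Fit per-group baselines and main effects
#'
#' Fits, within every replicate group k, the additive model
#' `y_ijk = y0k + m_ik + m_jk + eps` to the co-RNAi wells by (possibly
#' robust) least squares under the identifiability constraint
#' `sum_i m_ik = 0`. Only non-control, non-self-pair wells enter the fit;
#' single-gene and untreated controls are reserved for quality control.
#'
#' For `loss = "squared"` this is ordinary least squares per group, which on
#' balanced designs coincides with minimizing the sum of squared pair-mean
#' residuals. The robust variants are solved by iteratively reweighted least
#' squares (L1, Huber) or by concentration steps on the per-pair-per-group
#' mean residuals (LTS); non-convergence after `max_iter` iterations yields
#' a warning and `converged = FALSE`.
#'
#' @param screen a `normalized_screen`.
#' @param grouping `"biological"` (default; one parameter set per biological
#'   replicate), `"pooled"` (one set overall) or `"technical"` (one per
#'   technical replicate).
#' @param options a [robust_options()] object.
#' @return A `main_effect_fit`: list with `baseline` (named per group), `m`
#'   (reagents x groups matrix), `grouping`, `n_free_parameters`,
#'   `converged`, `options`.
#' @export
fit_main_effects <- function(screen, grouping = "biological",
                             options = robust_options()) {
  stopifnot(inherits(screen, "normalized_screen"))
  if (!inherits(options, "robust_options")) options <- do.call(robust_options, options)
  ids <- scored_reagents(screen)
  N <- length(ids)
  use <- !well_is_control(screen) & !well_is_self_pair(screen) &
    is.finite(screen$wells$value)
  grp <- replicate_group(screen, grouping)[use]
  grp <- droplevels(grp)
  w <- screen$wells[use, ]
  ri <- match(w$reagent_row, ids)
  rj <- match(w$reagent_col, ids)
  K <- nlevels(grp)

  ## precondition: every reagent in >= 2 distinct pairs in every group
  for (g in levels(grp)) {
    sel <- grp == g
    for (i in seq_len(N)) {
      partners <- unique(c(rj[sel & ri == i], ri[sel & rj == i]))
      if (length(partners) < 2)
        stop("rank-deficiency error: reagent '", ids[i],
             "' occurs in fewer than 2 pairs in group '", g, "'")
    }
  }

  y <- w$value
  cellkey <- paste(pair_key(w$reagent_row, w$reagent_col), grp)

  fit_once <- function(weights) {
    y0 <- numeric(K); m <- matrix(0, N, K,
                                  dimnames = list(ids, levels(grp)))
    for (gi in seq_len(K)) {
      sel <- grp == levels(grp)[gi]
      wts <- if (is.null(weights)) NULL else weights[sel]
      sol <- solve_group(y[sel], ri[sel], rj[sel], N, wts)
      y0[gi] <- sol$y0
      m[, gi] <- sol$m
    }
    names(y0) <- levels(grp)
    list(y0 = y0, m = m)
  }
  resid_of <- function(f) {
    gi <- as.integer(grp)
    y - f$y0[gi] - f$m[cbind(ri, gi)] - f$m[cbind(rj, gi)]
  }

  cur <- fit_once(NULL)
  converged <- TRUE
  if (options$loss != "squared") {
    converged <- FALSE
    for (it in seq_len(options$max_iter)) {
      e <- resid_of(cur)
      wts <- switch(options$loss,
        absolute = 1 / pmax(abs(e), 1e-8),
        huber = {
          s <- stats::mad(e)
          if (s <= 0) { converged <- TRUE; break }
          pmin(1, options$huber_c / pmax(abs(e / s), 1e-12))
        },
        lts = {
          cellmean <- tapply(e, cellkey, mean)
          h <- ceiling(options$lts_fraction * length(cellmean))
          keep <- names(sort(abs(cellmean)))[seq_len(h)]
          as.numeric(cellkey %in% keep)
        })
      nxt <- fit_once(wts)
      delta <- max(abs(c(nxt$y0 - cur$y0, nxt$m - cur$m)))
      cur <- nxt
      if (delta < options$tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("robust fit did not converge in ", options$max_iter,
              " iterations; returning last iterate")
  }

  structure(list(baseline = cur$y0, m = cur$m, grouping = grouping,
                 reagents = ids,
                 n_free_parameters = count_parameters(N, K),
                 converged = converged, options = options),
            class = "main_effect_fit")
}

#' @export
print.main_effect_fit <- function(x, ...) {
  cat(sprintf("main_effect_fit: %d reagents, %d %s group(s), %d free parameters (loss: %s)\n",
              nrow(x$m), ncol(x$m), x$grouping, x$n_free_parameters,
              x$options$loss))
  invisible(x)
}

#' Compute residuals and the pairwise interaction matrix
#'
#' For every co-RNAi well, the residual is
#' `eps_ijk = y_ijk - y0k - m_ik - m_jk`; the interaction score of pair
#' (i, j) is the mean of its residuals over all replicate measurements,
#' `w_ij = mean_k eps_ijk`, on the log2 scale. The matrix is symmetric with
#' an unavailable (NA) diagonal; pairs without wells are NA.
#'
#' @param screen the `normalized_screen` the fit was produced on.
#' @param fit a [fit_main_effects()] result.
#' @return A list of class `interaction_estimate` with `residuals`
#'   (data.frame: i, j, pair, group, plate, well row index, predicted, eps),
#'   `W` (symmetric N x N score matrix), `K` (per-pair replicate counts),
#'   and `reagents`.
#' @export
estimate_interactions <- function(screen, fit) {
  stopifnot(inherits(screen, "normalized_screen"),
            inherits(fit, "main_effect_fit"))
  ids <- fit$reagents
  use <- which(!well_is_control(screen) & !well_is_self_pair(screen) &
                 is.finite(screen$wells$value))
  w <- screen$wells[use, ]
  grp <- as.character(replicate_group(screen, fit$grouping)[use])
  if (!all(grp %in% colnames(fit$m)))
    stop("value error: screen contains replicate groups absent from the fit")
  ri <- match(w$reagent_row, ids)
  rj <- match(w$reagent_col, ids)
  gi <- match(grp, colnames(fit$m))
  pred <- fit$baseline[gi] + fit$m[cbind(ri, gi)] + fit$m[cbind(rj, gi)]
  eps <- w$value - pred
  key <- pair_key(w$reagent_row, w$reagent_col)

  N <- length(ids)
  W <- matrix(NA_real_, N, N, dimnames = list(ids, ids))
  Kmat <- matrix(0L, N, N, dimnames = list(ids, ids))
  mw <- tapply(eps, key, mean)
  ct <- table(key)
  ij <- do.call(rbind, strsplit(names(mw), ":", fixed = TRUE))
  a <- match(ij[, 1], ids); b <- match(ij[, 2], ids)
  W[cbind(a, b)] <- mw; W[cbind(b, a)] <- mw
  Kmat[cbind(a, b)] <- as.integer(ct[names(mw)])
  Kmat[cbind(b, a)] <- Kmat[cbind(a, b)]
  diag(W) <- NA_real_

  residuals <- data.frame(i = pmin(w$reagent_row, w$reagent_col),
                          j = pmax(w$reagent_row, w$reagent_col),
                          pair = key, group = grp, plate = w$plate,
                          well = use, predicted = unname(pred),
                          eps = unname(eps), stringsAsFactors = FALSE)
  structure(list(residuals = residuals, W = W, K = Kmat, reagents = ids),
            class = "interaction_estimate")
}

#' Local-regression fit diagnostic
#'
#' Estimates the local mean of the residuals as a function of the predicted
#' (no-interaction) value `y0k + m_ik + m_jk` with loess. Trends in this
#' curve indicate model misspecification; a well-specified fit gives a flat
#' curve near zero.
#'
#' @param est an [estimate_interactions()] result.
#' @param span loess span (default 0.5); widened with a warning if the fit
#'   fails with too few points.
#' @param n_grid number of evenly spaced grid points (default 100).
#' @return data.frame with columns `predicted`, `trend`.
#' @export
fit_diagnostic_trend <- function(est, span = 0.5, n_grid = 100L) {
  r <- est$residuals
  if (nrow(r) < 20) stop("value error: need at least 20 residuals")
  lo <- tryCatch(stats::loess(eps ~ predicted, data = r, span = span,
                              degree = 1),
                 error = function(e) NULL)
  while (is.null(lo) && span < 1) {
    span <- min(1, span * 1.5)
    warning("loess span widened to ", signif(span, 3))
    lo <- tryCatch(stats::loess(eps ~ predicted, data = r, span = span,
                                degree = 1),
                   error = function(e) NULL)
  }
  if (is.null(lo)) stop("value error: local regression failed")
  grid <- seq(min(r$predicted), max(r$predicted), length.out = n_grid)
  data.frame(predicted = grid,
             trend = unname(stats::predict(lo, newdata =
                                             data.frame(predicted = grid))))
}

#' Write fit parameters and interaction matrix as text tables
#'
#' @param fit a `main_effect_fit`.
#' @param est an `interaction_estimate`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fit_tables <- function(fit, est, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- rbind(
    data.frame(group = names(fit$baseline), reagent = "(baseline)",
               estimate = unname(fit$baseline), stringsAsFactors = FALSE),
    do.call(rbind, lapply(colnames(fit$m), function(g)
      data.frame(group = g, reagent = rownames(fit$m),
                 estimate = fit$m[, g], stringsAsFactors = FALSE))))
  utils::write.table(pars, file.path(dir, "fit_parameters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(est$W, file.path(dir, "interactions_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  up <- which(upper.tri(est$W), arr.ind = TRUE)
  tidy <- data.frame(i = rownames(est$W)[up[, 1]],
                     j = colnames(est$W)[up[, 2]],
                     w = est$W[up], K = est$K[up], stringsAsFactors = FALSE)
  utils::write.table(tidy, file.path(dir, "interactions_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
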