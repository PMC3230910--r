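#' Exponential growth under perturbations
#'
#' Cell number after time `t` under an exponential growth model in which
#' perturbations act multiplicatively on the growth rate:
#' `n(t) = n0 exp((1 + sum(m x)) k t)`. The log phenotype relative to the
#' unperturbed culture, `y = log(n / n_wt)` with `n_wt = n0 exp(k t)`,
#' equals `sum(m x) k t` exactly, so on the log scale non-interacting
#' perturbations are exactly additive — the reason the analysis operates on
#' log-transformed readouts.
#'
#' @param n0 initial cell number (> 0).
#' @param k growth rate of unperturbed cells (per unit time).
#' @param t duration (>= 0).
#' @param m per-perturbation relative effects (dimensionless).
#' @param x perturbation indicators in \{0, 1\}, same length as `m`.
#' @return list with `n` (cell number at `t`) and `y` (log phenotype,
#'   natural log).
#' @export
grow <- function(n0, k, t, m = numeric(0), x = numeric(0)) {
  stopifnot(n0 > 0, t >= 0, length(m) == length(x))
  n <- n0 * exp((1 + sum(m * x)) * k * t)
  list(n = n, y = sum(m * x) * k * t)
}

#' Relative growth rate from sampled trajectories
#'
#' The dimensionless ratio of the maximal per-capita growth rate
#' `d log n / dt` of a perturbed trajectory to the wild-type maximum.
#' Under exponential growth this equals `1 + m`. Derivatives are taken by
#' central differences on the log trajectory.
#'
#' @param n,t perturbed trajectory (cell numbers, strictly positive) and its
#'   time points (>= 3).
#' @param n_wt,t_wt wild-type trajectory and time points.
#' @return `rho`, a single number; 1 means no growth effect.
#' @export
relative_growth_rate <- function(n, t, n_wt, t_wt) {
  max_rate <- function(nn, tt) {
    if (length(nn) < 3 || length(nn) != length(tt))
      stop("value error: need >= 3 matched (n, t) points")
    if (any(nn <= 0)) stop("value error: non-positive trajectory values")
    max(diff(log(nn)) / diff(tt))
  }
  max_rate(n, t) / max_rate(n_wt, t_wt)
}

#' Gap between multiplicative and additive neutrality
#'
#' Two single-perturbation relative effects `m1`, `m2` predict the neutral
#' double perturbation as `(1 + m1)(1 + m2)` on the multiplicative scale and
#' `1 + m1 + m2` on the additive scale; the discrepancy is exactly
#' `m1 * m2`, negligible for small effects but not for strong ones.
#'
#' @param m1,m2 relative effects.
#' @return `(1 + m1) (1 + m2) - (1 + m1 + m2)`.
#' @export
neutrality_gap <- function(m1, m2) {
  (1 + m1) * (1 + m2) - (1 + m1 + m2)
}

#' Simulation configuration for a synthetic criss-cross screen
#'
#' Defaults emulate the benchmark screen: 16 reagents on 16 x 24 plates with
#' positive/negative control columns 7 and 14, 5 plates x 2 biological
#' replicates (so 20 measurements per pair), log2-additive main effects
#' drawn uniformly on `[-1, 1]` (centered), Gaussian noise of sd 0.1 log2
#' units, per-plate offsets uniform on `[-0.5, 0.5]`, and biological
#' replicate heterogeneity of sd 0.05 on baselines and main effects.
#' Positive controls sit 4 log2 units below baseline with sd 0.1.
#'
#' @param N number of scored reagents.
#' @param bioreps,plates_per_biorep replicate structure.
#' @param baseline log2 baseline of the first biological replicate.
#' @param sigma measurement noise sd, log2 units.
#' @param main_effects optional N x bioreps matrix of main effects (log2);
#'   drawn when `NULL`.
#' @param interactions data.frame with columns `i`, `j`, `w` of planted
#'   interaction effects (log2); `NULL` for none.
#' @param plate_offset_range half-width of the uniform per-plate offsets.
#' @param biorep_sd sd of biological-replicate perturbations of baseline and
#'   main effects.
#' @param sigma_w_bio sd of per-pair, per-biological-replicate interaction
#'   jitter (biological interaction variability; 0 by default).
#' @param var_prior `NULL` for homoscedastic noise, or
#'   `list(d0 =, s0_sq =)` to draw per-pair noise variances from a scaled
#'   inverse-chi-square prior (gene-pair dependent variance).
#' @param controls list: log2 shifts relative to baseline of the positive
#'   and negative controls, and their sd.
#' @param control_columns,include_self_pairs,plate_rows,plate_cols passed to
#'   [generate_crisscross_design()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = 16L, bioreps = 2L, plates_per_biorep = 5L,
                       baseline = 10, sigma = 0.1,
                       main_effects = NULL, interactions = NULL,
                       plate_offset_range = 0.5, biorep_sd = 0.05,
                       sigma_w_bio = 0, var_prior = NULL,
                       controls = list(positive = -4, negative = 0, sd = 0.1),
                       control_columns = list(positive = 7L, negative = 14L),
                       include_self_pairs = FALSE,
                       plate_rows = 16L, plate_cols = 24L) {
  if (sigma < 0) stop("config error: sigma must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a criss-cross co-RNAi screen with known ground truth
#'
#' Builds the plate layout with [generate_crisscross_design()], then draws
#' every pair-well on the log2 scale as
#' `y = y0k + m_ik + m_jk + w_ij + delta_p + noise` and emits the raw-scale
#' readout `2^y`. Control wells are drawn around their configured shifts
#' from baseline and also receive the plate offset. The full resolved truth
#' (baselines, main effects, interaction matrix, plate offsets, per-pair
#' sds) is retained for recovery testing. The same seed reproduces the
#' screen exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for all randomness.
#' @return list of class `simulated_screen` with `screen` (a
#'   `screen_table`) and `truth`.
#' @export
simulate_screen <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  N <- config$N
  ids <- sprintf("g%02d", seq_len(N))
  Kb <- config$bioreps

  m <- config$main_effects
  if (is.null(m)) {
    m1 <- stats::runif(N, -1, 1)
    m1 <- m1 - mean(m1)
    m <- matrix(NA_real_, N, Kb)
    m[, 1] <- m1
    if (Kb > 1) for (b in 2:Kb) {
      mb <- m1 + stats::rnorm(N, 0, config$biorep_sd)
      m[, b] <- mb - mean(mb)
    }
  }
  rownames(m) <- ids
  y0 <- config$baseline + c(0, stats::rnorm(Kb - 1, 0, config$biorep_sd))

  W <- matrix(0, N, N, dimnames = list(ids, ids))
  if (!is.null(config$interactions)) {
    it <- config$interactions
    unk <- setdiff(c(it$i, it$j), ids)
    if (length(unk))
      stop("config error: interaction for unknown reagent(s): ",
           paste(unk, collapse = ", "))
    for (r in seq_len(nrow(it))) {
      W[it$i[r], it$j[r]] <- it$w[r]
      W[it$j[r], it$i[r]] <- it$w[r]
    }
  }

  design <- generate_crisscross_design(
    ids, plates_per_biorep = config$plates_per_biorep,
    bioreps = Kb, control_columns = config$control_columns,
    include_self_pairs = config$include_self_pairs,
    plate_rows = config$plate_rows, plate_cols = config$plate_cols)

  plates <- unique(design$wells$plate)
  delta <- stats::setNames(stats::runif(length(plates),
                                        -config$plate_offset_range,
                                        config$plate_offset_range), plates)

  ## per-pair noise sd (optionally heteroscedastic)
  up <- which(upper.tri(W), arr.ind = TRUE)
  pkeys <- pair_key(ids[up[, 1]], ids[up[, 2]])
  sd_pair <- if (is.null(config$var_prior)) {
    stats::setNames(rep(config$sigma, length(pkeys)), pkeys)
  } else {
    vp <- config$var_prior
    stats::setNames(sqrt(vp$d0 * vp$s0_sq /
                           stats::rchisq(length(pkeys), vp$d0)), pkeys)
  }
  ## per-pair, per-biorep interaction jitter
  w_bio <- matrix(0, length(pkeys), Kb, dimnames = list(pkeys, NULL))
  if (config$sigma_w_bio > 0)
    w_bio[] <- stats::rnorm(length(pkeys) * Kb, 0, config$sigma_w_bio)

  w <- design$wells
  ctrl <- well_is_control(design)
  self <- well_is_self_pair(design)
  bi <- match(w$bio_rep, sprintf("b%d", seq_len(Kb)))
  key <- pair_key(w$reagent_row, w$reagent_col)
  y <- numeric(nrow(w))

  pw <- which(!ctrl & !self)
  ri <- match(w$reagent_row[pw], ids); rj <- match(w$reagent_col[pw], ids)
  y[pw] <- y0[bi[pw]] + m[cbind(ri, bi[pw])] + m[cbind(rj, bi[pw])] +
    W[cbind(ri, rj)] + w_bio[cbind(match(key[pw], pkeys), bi[pw])] +
    delta[w$plate[pw]] +
    stats::rnorm(length(pw), 0, sd_pair[key[pw]])

  sf <- which(self)
  if (length(sf)) {
    rs <- match(w$reagent_row[sf], ids)
    y[sf] <- y0[bi[sf]] + 2 * m[cbind(rs, bi[sf])] + delta[w$plate[sf]] +
      stats::rnorm(length(sf), 0, config$sigma)
  }

  cw <- which(ctrl)
  if (length(cw)) {
    role <- stats::setNames(design$reagents$control_role,
                            design$reagents$id)
    shift <- ifelse(role[w$reagent_col[cw]] == "positive",
                    config$controls$positive, config$controls$negative)
    y[cw] <- y0[bi[cw]] + shift + delta[w$plate[cw]] +
      stats::rnorm(length(cw), 0, config$controls$sd)
  }

  design$wells$readout <- 2^y
  truth <- list(config = config, seed = seed, reagents = ids, y0 = y0,
                m = m, W = W, delta = delta, sd_pair = sd_pair,
                w_bio = w_bio)
  structure(list(screen = design, truth = truth),
            class = "simulated_screen")
}

#' Scalability-scale simulation: many pairs, few replicates
#'
#' Emulates a large screen of 84 reagents (3486 pairs) measured with little
#' replication: one plate per biological replicate on a virtual 84 x 86
#' geometry, so each pair is measured 4 times (2 symmetric positions x 2
#' biological replicates). A fixed number of non-null pairs (default 472),
#' spread evenly over the pair list, carry interaction effects of
#' alternating sign with magnitudes just above the detectability floor of
#' 4 standard errors (4 sigma / sqrt(K) = 0.2 log2 units at the default
#' noise), so essentially every non-null yields a small p-value while the
#' total interaction mass stays small: the least-squares criterion lets
#' main effects absorb interaction signal, so a large planted mass would
#' shift the null pairs' residuals and contaminate false-null estimation.
#' Used to study the [schweder_spjotvoll()] estimate at scale.
#'
#' @param N number of reagents (default 84).
#' @param n_nonnull number of planted non-null pairs (default 472).
#' @param w_range magnitude range of the planted effects.
#' @param ... passed to [sim_config()].
#' @return A [sim_config()]. Planted pairs and effects are deterministic.
#' @export
scalability_config <- function(N = 84L, n_nonnull = 472L,
                               w_range = c(0.2, 0.25), ...) {
  ids <- sprintf("g%02d", seq_len(N))
  combs <- t(utils::combn(ids, 2))
  m <- nrow(combs)
  stopifnot(n_nonnull <= m)
  pick <- unique(round(seq(1, m, length.out = n_nonnull)))
  stopifnot(length(pick) == n_nonnull)
  w <- rep_len(seq(w_range[1], w_range[2], length.out = 8L), n_nonnull) *
    rep_len(c(1, -1), n_nonnull)
  sim_config(N = N, bioreps = 2L, plates_per_biorep = 1L,
             interactions = data.frame(i = combs[pick, 1],
                                       j = combs[pick, 2], w = w,
                                       stringsAsFactors = FALSE),
             control_columns = list(),
             plate_rows = N, plate_cols = N + 2L, ...)
}

#' Write the ground-truth interaction table of a simulated screen
#'
#' @param sim a [simulate_screen()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  W <- sim$truth$W
  up <- which(upper.tri(W), arr.ind = TRUE)
  tab <- data.frame(i = rownames(W)[up[, 1]], j = colnames(W)[up[, 2]],
                    w_true = W[up], stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
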