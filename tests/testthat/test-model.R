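test_that("parameter counting follows K(N+1) - K", {
  expect_equal(count_parameters(16, 2), 32L)
  expect_equal(count_parameters(16, 20), 320L)
  expect_equal(count_parameters(16, 1), 16L)
  expect_error(count_parameters(1, 1), "value error")
})

test_that("noiseless additive data is recovered exactly", {
  cfg <- sim_config(sigma = 0)                  # W = 0, offsets still drawn
  sim <- simulate_screen(cfg, seed = 4)
  out <- run_pipeline_core(sim)
  expect_lt(max(abs(out$est$residuals$eps)), 1e-9)
  expect_lt(max(abs(out$est$W), na.rm = TRUE), 1e-9)
  # main effects (already centered per group in the truth) match exactly
  expect_equal(unname(out$fit$m), unname(sim$truth$m), tolerance = 1e-9)
  expect_equal(out$fit$n_free_parameters, 32L)
})

test_that("a saturated 3-reagent fit solves the hand-worked system", {
  s <- toy_normalized_screen(data.frame(
    i = c("A", "A", "B"), j = c("B", "C", "C"), group = "g1",
    value = c(1, 2, 3), stringsAsFactors = FALSE))
  fit <- fit_main_effects(s)
  expect_equal(unname(fit$baseline), 2)
  expect_equal(unname(fit$m[, 1]), c(-1, 0, 1))
  est <- estimate_interactions(s, fit)
  expect_lt(max(abs(est$residuals$eps)), 1e-12)
})

test_that("squared-loss fit matches the constrained normal-equations oracle", {
  for (seed in 1:6) {
    N <- sample(3:6, 1)
    K <- sample(1:2, 1)
    df <- random_toy_screen(N, K, reps = sample(2:3, 1), seed = seed)
    s <- toy_normalized_screen(df)
    fit <- fit_main_effects(s)
    orc <- fit_oracle(df$value, df$i, df$j, df$group,
                      sort(unique(c(df$i, df$j))), sort(unique(df$group)))
    expect_equal(unname(fit$baseline), unname(orc$y0), tolerance = 1e-8)
    expect_equal(unname(fit$m), unname(orc$m), tolerance = 1e-8)
    expect_lt(max(abs(colSums(fit$m))), 1e-9)   # sum-to-zero per group
  }
})

test_that("interaction scores are symmetric and storage-order invariant", {
  sim <- simulate_screen(default_benchmark_config(), seed = 6)
  ns <- normalize_plates(sim$screen)
  fit <- fit_main_effects(ns)
  est1 <- estimate_interactions(ns, fit)
  expect_true(isSymmetric(est1$W))
  expect_true(all(is.na(diag(est1$W))))
  ns2 <- ns
  tmp <- ns2$wells$reagent_row
  ns2$wells$reagent_row <- ns2$wells$reagent_col
  ns2$wells$reagent_col <- tmp
  est2 <- estimate_interactions(ns2, fit_main_effects(ns2))
  expect_equal(est1$W, est2$W, tolerance = 1e-12)
})

test_that("interaction scores absorb a constant shift of one plate", {
  sim <- simulate_screen(default_benchmark_config(), seed = 8)
  base <- run_pipeline_core(sim)
  shifted <- sim$screen
  on_p <- shifted$wells$plate == "b1_p2"
  shifted$wells$readout[on_p] <- shifted$wells$readout[on_p] * 2^1.7
  out <- run_pipeline_core(list(screen = shifted) |>
                             structure(class = "simulated_screen"))
  expect_equal(base$est$W, out$est$W, tolerance = 1e-9)
})

test_that("a planted interaction is estimated at its expected magnitude", {
  ids <- sprintf("g%02d", 1:16)
  cfg <- sim_config(interactions = data.frame(i = "g01", j = "g02", w = 0.5))
  sim <- simulate_screen(cfg, seed = 10)
  out <- run_pipeline_core(sim)
  # conservative criterion: single-pair shrinkage factor 104/120 at N = 16,
  # se ~ sigma/sqrt(20); allow 4 standard errors
  expect_lt(abs(out$est$W["g01", "g02"] - 0.5 * 104 / 120), 0.1)
  expect_equal(out$est$K["g01", "g02"], 20L)
})

test_that("the default planted set shrinks by the single-pair factor", {
  cfg <- default_benchmark_config(sigma = 0, biorep_sd = 0)
  sim <- simulate_screen(cfg, seed = 1)
  out <- run_pipeline_core(sim)
  it <- sim$truth$config$interactions
  ratio <- mapply(function(i, j, w) out$est$W[i, j] / w, it$i, it$j, it$w)
  expect_true(all(ratio > 0.8 & ratio < 0.92))
})

test_that("robust losses agree with least squares on clean additive data", {
  set.seed(13)
  ids <- LETTERS[1:6]
  combs <- t(combn(ids, 2))
  m_true <- stats::setNames(rnorm(6), ids)
  m_true <- m_true - mean(m_true)
  df <- do.call(rbind, lapply(1:2, function(r)
    data.frame(i = combs[, 1], j = combs[, 2], group = "g1",
               value = 3 + m_true[combs[, 1]] + m_true[combs[, 2]])))
  s <- toy_normalized_screen(df)
  ref <- fit_main_effects(s)
  for (loss in c("absolute", "huber", "lts")) {
    rf <- fit_main_effects(s, options = robust_options(loss = loss))
    expect_true(rf$converged)
    # at zero residuals every loss has the same minimizer
    expect_equal(rf$m, ref$m, tolerance = 1e-6, label = loss)
  }
  # Huber with an enormous tuning constant IS least squares, even off-model
  dfn <- random_toy_screen(6, 1, reps = 3, seed = 14)
  sn <- toy_normalized_screen(dfn)
  refn <- fit_main_effects(sn)
  rfn <- fit_main_effects(sn, options = robust_options(loss = "huber",
                                                       huber_c = 1e6))
  expect_equal(rfn$m, refn$m, tolerance = 1e-6)
  expect_equal(rfn$baseline, refn$baseline, tolerance = 1e-6)
})

test_that("L1 and LTS resist a gross outlier better than least squares", {
  set.seed(21)
  ids <- LETTERS[1:8]
  combs <- t(combn(ids, 2))
  m_true <- stats::setNames(seq(-0.7, 0.7, length.out = 8), ids)
  m_true <- m_true - mean(m_true)
  df <- do.call(rbind, lapply(1:2, function(r)
    data.frame(i = combs[, 1], j = combs[, 2], group = "g1",
               value = 5 + m_true[combs[, 1]] + m_true[combs[, 2]] +
                 rnorm(nrow(combs), 0, 0.05))))
  df$value[1] <- df$value[1] + 10                # one gross outlier well
  s <- toy_normalized_screen(df)
  err <- function(fit) max(abs(fit$m[, 1] - m_true[rownames(fit$m)]))
  e_sq <- err(fit_main_effects(s))
  e_l1 <- err(fit_main_effects(s, options = robust_options(loss = "absolute")))
  e_lts <- err(fit_main_effects(s, options = robust_options(loss = "lts")))
  expect_lt(e_l1, e_sq)
  expect_lt(e_lts, e_sq)
})

test_that("unidentifiable inputs raise rank-deficiency errors", {
  df <- data.frame(i = c("A", "A"), j = c("B", "B"), group = "g1",
                   value = c(1, 2))
  expect_error(fit_main_effects(toy_normalized_screen(df)),
               "rank-deficiency")
  expect_error(robust_options(loss = "nonsense"))
  expect_error(robust_options(lts_fraction = 0.2), "option error")
})

test_that("fit diagnostic trend is flat for a correct model and finds bias", {
  sim <- simulate_screen(default_benchmark_config(), seed = 30)
  out <- run_pipeline_core(sim)
  tr <- fit_diagnostic_trend(out$est)
  expect_equal(nrow(tr), 100L)
  expect_lt(max(abs(tr$trend), na.rm = TRUE), 0.05)

  # inject a linear residual trend and recover its slope
  est2 <- out$est
  ctr <- mean(est2$residuals$predicted)
  est2$residuals$eps <- est2$residuals$eps +
    0.2 * (est2$residuals$predicted - ctr)
  tr2 <- fit_diagnostic_trend(est2)
  core <- tr2[tr2$predicted > quantile(est2$residuals$predicted, 0.1) &
                tr2$predicted < quantile(est2$residuals$predicted, 0.9), ]
  slope <- coef(lm(trend ~ predicted, data = core))[2]
  expect_lt(abs(slope - 0.2), 0.02)

  expect_error(fit_diagnostic_trend(
    structure(list(residuals = out$est$residuals[1:5, ]),
              class = "interaction_estimate")), "value error")
})
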