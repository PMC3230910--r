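test_that("ordinary t-test matches closed forms and is scale invariant", {
  r <- ordinary_t_test(c(1, -1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- ordinary_t_test(c(0.5, 0.7, 0.9))
  expect_equal(r$t, 0.7 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # closed-form Student CDF for df = 2: P(T > t) = (1 - t/sqrt(t^2+2))/2
  p_closed <- 2 * (1 - r$t / sqrt(r$t^2 + 2)) / 2
  expect_equal(r$p, p_closed, tolerance = 1e-10)
  expect_equal(r$p, 0.02615, tolerance = 1e-3)

  for (c0 in c(0.1, 3, 250)) {
    rs <- ordinary_t_test(c(0.5, 0.7, 0.9) * c0)
    expect_equal(rs$t, r$t, tolerance = 1e-12)
    expect_equal(rs$p, r$p, tolerance = 1e-12)
  }

  expect_true(is.na(ordinary_t_test(c(1))$t))
  expect_equal(ordinary_t_test(c(2, 2, 2))$p, 0)
  expect_equal(ordinary_t_test(c(0, 0))$p, 1)
})

test_that("moderation prior: degenerate branch and moment-matched branch", {
  pr <- fit_moderation_prior(rep(0.02, 10), df = 19)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.02, tolerance = 1e-12)
  lf0 <- limma::fitFDist(rep(0.02, 10), df1 = 19)
  expect_equal(pr$s0_sq, lf0$scale, tolerance = 1e-9)

  # independent oracle: limma's moment-matching of the scaled-F model
  pr2 <- fit_moderation_prior(c(0.01, 0.04), df = 19)
  lf <- limma::fitFDist(c(0.01, 0.04), df1 = 19)
  expect_equal(pr2$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr2$s0_sq, lf$scale, tolerance = 1e-6)

  set.seed(5)
  s2 <- 0.02 * rchisq(150, 8) / 8 * rchisq(150, 5) / 5
  lf <- limma::fitFDist(s2, df1 = 8)
  pr3 <- fit_moderation_prior(s2, df = 8)
  expect_equal(pr3$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr3$s0_sq, lf$scale, tolerance = 1e-6)
})

test_that("moderation prior recovers planted hyperparameters", {
  set.seed(77)
  d0s <- s0s <- numeric(100)
  for (r in 1:100) {
    s2 <- 4 * 0.01 / rchisq(120, 4)          # scaled inverse-chi-square draws
    s2 <- s2 * rchisq(120, 19) / 19          # sampling noise at df = 19
    pr <- fit_moderation_prior(s2, df = 19)
    d0s[r] <- pr$d0; s0s[r] <- pr$s0_sq
  }
  expect_gt(mean(d0s), 2.5)
  expect_lt(mean(d0s), 6.5)
  expect_lt(abs(mean(s0s) / 0.01 - 1), 0.3)
})

test_that("moderated t reproduces its two analytic limits", {
  set.seed(31)
  w <- rnorm(40, 0, 0.3); s2 <- rexp(40, 10); K <- 4L; df <- K - 1L
  # d0 = 0: no shrinkage, ordinary t
  m0 <- moderated_t_test(w, s2, df, K, list(d0 = 0, s0_sq = 1))
  expect_equal(m0$t, w / sqrt(s2 / K), tolerance = 1e-12)
  # d0 = Inf: constant variance, statistic proportional to the effect size
  mi <- moderated_t_test(w, s2, df, K, list(d0 = Inf, s0_sq = 0.01))
  expect_equal(mi$t, w / (0.1 / 2), tolerance = 1e-12)
  expect_equal(order(abs(mi$t)), order(abs(w)))
  expect_equal(mi$p, 2 * pnorm(-abs(mi$t)), tolerance = 1e-12)
  # hand example in the infinite-prior limit
  one <- moderated_t_test(0.3, 0.04, 3, 4, list(d0 = Inf, s0_sq = 0.01))
  expect_equal(one$t, 6)
  expect_equal(one$p, 2 * pnorm(-6), tolerance = 1e-12)
  # shrunken variance interpolates the prior and the sample variance
  mf <- moderated_t_test(0.2, 0.03, 3, 4, list(d0 = 5, s0_sq = 0.01))
  expect_equal(mf$t, 0.2 / sqrt(((5 * 0.01 + 3 * 0.03) / 8) / 4),
               tolerance = 1e-12)
  # cross-check the posterior variance against limma::squeezeVar
  sq <- limma::squeezeVar(s2, df = df)
  ms <- moderated_t_test(w, s2, df, K,
                         list(d0 = sq$df.prior, s0_sq = sq$var.prior))
  expect_equal(ms$t, w / sqrt(sq$var.post / K), tolerance = 1e-10)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(9)
  for (r in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_hand(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in raw p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "value error")
})

test_that("Schweder-Spjotvoll counting and the two-point line fit", {
  r <- schweder_spjotvoll(c(0.125, 0.375, 0.625, 0.875))
  expect_equal(r$n_false_null, 0)
  r2 <- schweder_spjotvoll(c(0.001, 0.002, 0.003, 0.6, 0.8))
  expect_equal(r2$n_false_null, 1)          # N(0.5) = 2, 5 - (2*2 - 0)
  expect_true(all(diff(r2$points$y) >= 0))  # graph non-decreasing in x
  expect_true(all(r2$points$y >= 0 & r2$points$y <= r2$m))
  expect_error(schweder_spjotvoll(c(0.1, 0.2)), "value error")
  # estimate floored at zero even when N(0.5) overshoots by chance
  expect_equal(schweder_spjotvoll(rep(0.9, 10))$n_false_null, 0)
})

test_that("benchmark reference construction and boundaries", {
  fake <- data.frame(pair = sprintf("a:%02d", 1:6),
                     p_ordinary = c(1e-5, 5e-4, 0.002, 0.5, 0.5, 0.5))
  ref <- build_benchmark_reference(fake)
  expect_equal(ref$positives, fake$pair[1:2])
  expect_equal(length(ref$negatives), 4)
  expect_warning(build_benchmark_reference(
    data.frame(pair = "a:b", p_ordinary = 0.5)), "no positives")
  ref1 <- build_benchmark_reference(fake, alpha = 1)
  expect_equal(sort(ref1$positives), sort(fake$pair))
})

test_that("pseudo-ROC: perfect, random and constant rankings", {
  ref <- structure(list(positives = sprintf("p:%02d", 1:10),
                        negatives = sprintf("n:%02d", 1:20)),
                   class = "benchmark_reference")
  perfect <- stats::setNames(c(seq(2, 3, length.out = 10),
                               seq(0, 1, length.out = 20)),
                             c(ref$positives, ref$negatives))
  rc <- pseudo_roc(perfect, ref)
  expect_equal(rc$auc, 1)
  expect_equal(max(rc$tpr[rc$fpr == 0]), 1)

  # independent AUC oracle on a noisy ranking
  set.seed(12)
  noisy <- stats::setNames(rnorm(30, rep(c(1, 0), c(10, 20))),
                           c(ref$positives, ref$negatives))
  rc2 <- pseudo_roc(noisy, ref)
  oracle <- pROC::auc(pROC::roc(
    response = names(noisy) %in% ref$positives, predictor = unname(noisy),
    quiet = TRUE, direction = "<"))
  expect_equal(rc2$auc, as.numeric(oracle), tolerance = 1e-10)

  # null rankings average to AUC 1/2
  set.seed(101)
  ref2 <- structure(list(positives = sprintf("p:%02d", 1:60),
                         negatives = sprintf("n:%02d", 1:60)),
                    class = "benchmark_reference")
  aucs <- replicate(200, {
    sc <- stats::setNames(rnorm(120), c(ref2$positives, ref2$negatives))
    pseudo_roc(sc, ref2)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  expect_warning(
    pseudo_roc(stats::setNames(rep(1, 30), names(perfect)), ref),
    "constant")
  # p-value orientation: smaller is stronger
  pv <- stats::setNames(c(rep(1e-4, 10), runif(20, 0.2, 1)), names(perfect))
  expect_equal(pseudo_roc(pv, ref, higher_is_stronger = FALSE)$auc, 1)
})

test_that("vertical averaging preserves the grid and orders areas", {
  ref <- structure(list(positives = c("a:b", "c:d"),
                        negatives = c("e:f", "g:h", "i:j")),
                   class = "benchmark_reference")
  s1 <- stats::setNames(c(5, 4, 3, 2, 1), c("a:b", "c:d", "e:f", "g:h", "i:j"))
  s2 <- stats::setNames(c(1, 2, 3, 4, 5), names(s1))
  r1 <- pseudo_roc(s1, ref); r2 <- pseudo_roc(s2, ref)
  avg <- average_roc(list(r1, r2))
  expect_equal(length(avg$grid_tpr), 101L)
  expect_true(all(diff(avg$grid_tpr) >= -1e-12))
  # trapezoids are linear in TPR, so the average curve has the average area
  grid_auc <- function(r) sum(diff(r$grid) * (head(r$grid_tpr, -1) +
                                                tail(r$grid_tpr, -1)) / 2)
  expect_equal(avg$auc, mean(c(grid_auc(r1), grid_auc(r2))),
               tolerance = 1e-10)
})

test_that("pair tests assemble effects, both t-tests and FDR columns", {
  sim <- simulate_screen(default_benchmark_config(), seed = 15)
  out <- run_pipeline_core(sim)
  tt <- out$tests
  expect_equal(nrow(tt), 120L)
  expect_true(all(tt$K == 20L))
  expect_true(all(tt$p_ordinary >= 0 & tt$p_ordinary <= 1))
  expect_true(all(tt$p_ordinary_adj >= tt$p_ordinary - 1e-12))
  expect_true(all(tt$p_moderated_adj >= tt$p_moderated - 1e-12))
  # effects agree with the interaction matrix
  expect_equal(tt$w, out$est$W[cbind(tt$i, tt$j)], tolerance = 1e-12)
  # the planted pairs dominate both rankings
  pk <- planted_keys(sim)
  expect_true(all(tt$p_moderated_adj[tt$pair %in% pk] < 0.1))
  expect_true(all(abs(tt$w[tt$pair %in% pk]) >
                    max(abs(tt$w[!tt$pair %in% pk]))))
})

test_that("plate-center jitter makes biological-grouping tests conservative", {
  # the shorth's plate-to-plate sampling noise cancels out of w-hat but
  # inflates the within-pair sd when baselines are shared across plates;
  # error control remains valid (below nominal), just not exact
  p_ord <- numeric(0); s_all <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_screen(sim_config(), seed = 9500 + s)      # W = 0
    ns <- normalize_plates(sim$screen)
    tt <- pair_tests(estimate_interactions(ns,
                                           fit_main_effects(ns, "biological")))
    p_ord <- c(p_ord, tt$p_ordinary)
    s_all <- c(s_all, tt$s)
  }
  expect_lt(mean(p_ord < 0.05), 0.05)        # conservative, never inflated
  expect_gt(mean(s_all), 0.1)                # sd inflated above sigma
})
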