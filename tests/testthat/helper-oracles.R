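# Independent oracles, deliberately implemented differently from the package.

# brute-force shorth: enumerate every contiguous half-window explicitly
shorth_brute <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- ceiling(n / 2)
  wins <- lapply(seq_len(n - h + 1L), function(i) x[i:(i + h - 1L)])
  rng <- sapply(wins, function(w) max(w) - min(w))
  tol <- sqrt(.Machine$double.eps) * max(1, abs(diff(range(x))))
  best <- wins[rng <= min(rng) + tol]
  mean(sapply(best, function(w) (min(w) + max(w)) / 2))
}

# generic constrained normal-equations (KKT) solver for the additive model:
# y ~ y0[g] + m[i,g] + m[j,g], sum_i m[i,g] = 0 per group
fit_oracle <- function(y, i, j, g, ids, groups) {
  N <- length(ids); K <- length(groups)
  p <- K * (N + 1)
  X <- matrix(0, length(y), p)
  col_y0 <- function(gi) (gi - 1) * (N + 1) + 1
  col_m <- function(gi, ri) (gi - 1) * (N + 1) + 1 + ri
  for (r in seq_along(y)) {
    gi <- match(g[r], groups)
    X[r, col_y0(gi)] <- 1
    X[r, col_m(gi, match(i[r], ids))] <- X[r, col_m(gi, match(i[r], ids))] + 1
    X[r, col_m(gi, match(j[r], ids))] <- X[r, col_m(gi, match(j[r], ids))] + 1
  }
  C <- matrix(0, K, p)
  for (gi in seq_len(K)) C[gi, col_m(gi, seq_len(N))] <- 1
  A <- rbind(cbind(crossprod(X), t(C)),
             cbind(C, matrix(0, K, K)))
  b <- c(crossprod(X, y), rep(0, K))
  sol <- solve(A, b)[seq_len(p)]
  list(y0 = sol[col_y0(seq_len(K))],
       m = matrix(sol[-col_y0(seq_len(K))], N, K,
                  dimnames = list(ids, groups)))
}

# hand step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  q_sorted <- sapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))))
  q[o] <- q_sorted
  q
}

# build a normalized_screen directly from (i, j, group, value) records,
# bypassing plates/readouts, for fitting small hand-constructed cases
toy_normalized_screen <- function(df) {
  df$group <- as.character(df$group)
  wells <- do.call(rbind, lapply(split(df, df$group), function(d) {
    n <- nrow(d)
    data.frame(plate = d$group, row = ((seq_len(n) - 1) %/% 24) + 1,
               col = ((seq_len(n) - 1) %% 24) + 1,
               reagent_row = d$i, reagent_col = d$j,
               readout = 2^d$value, bio_rep = d$group, tech_rep = "t1",
               value = d$value, stringsAsFactors = FALSE)
  }))
  rownames(wells) <- NULL
  ids <- sort(unique(c(df$i, df$j)))
  reg <- data.frame(id = ids, target = ids, control_role = "none",
                    stringsAsFactors = FALSE)
  s <- screen_table(wells[, setdiff(names(wells), "value")], reg,
                    plate_rows = max(wells$row), plate_cols = 24)
  s$wells$value <- wells$value
  s$centers <- stats::setNames(rep(0, length(unique(wells$plate))),
                               unique(wells$plate))
  class(s) <- c("normalized_screen", class(s))
  s
}

# random small complete-design screen for oracle comparison
random_toy_screen <- function(N, K, reps = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%d", seq_len(N))
  groups <- sprintf("gr%d", seq_len(K))
  combs <- t(utils::combn(ids, 2))
  df <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(seq_len(reps), function(r)
      data.frame(i = combs[, 1], j = combs[, 2], group = g,
                 value = stats::rnorm(nrow(combs)),
                 stringsAsFactors = FALSE)))))
  df
}

# spec's planted-complex configuration: three reagents sharing one
# interaction generator (identical profiles across eight partners)
complex_config <- function() {
  members <- c("g01", "g02", "g03")
  partners <- sprintf("g%02d", 4:11)
  v <- c(1, -0.9, 0.8, -0.7, 0.6, -0.5, 0.45, -0.4)
  ints <- rbind(
    do.call(rbind, lapply(members, function(mm)
      data.frame(i = mm, j = partners, w = v, stringsAsFactors = FALSE))),
    data.frame(i = c("g01", "g01", "g02"), j = c("g02", "g03", "g03"),
               w = 0.6, stringsAsFactors = FALSE))
  sim_config(interactions = ints)
}

run_pipeline_core <- function(sim, grouping = "biological") {
  ns <- normalize_plates(sim$screen)
  fit <- fit_main_effects(ns, grouping = grouping)
  est <- estimate_interactions(ns, fit)
  list(ns = ns, fit = fit, est = est, tests = pair_tests(est))
}

planted_keys <- function(sim) {
  it <- sim$truth$config$interactions
  if (is.null(it)) character(0) else pair_key(it$i, it$j)
}
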