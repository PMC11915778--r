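# Independent natural-cubic-spline oracle: truncated power basis of a cubic
# spline with the same knots, constrained to be linear outside the boundary
# knots. Spans the same function space as any natural cubic spline basis on
# those knots.
natural_tp_basis <- function(x, interior, boundary) {
  knots <- c(boundary[1], interior, boundary[2])
  K <- length(knots)
  d <- function(j) {
    (pmax(x - knots[j], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[j])
  }
  out <- cbind(x)
  if (K >= 3) {
    for (j in seq_len(K - 2)) out <- cbind(out, d(j) - d(K - 1))
  }
  out
}

test_that("spline basis is linear-tailed, quantile-knotted, and spans the textbook space", {
  x <- seq_len(100)
  b1 <- ncs_basis(x, df = 1)
  expect_equal(ncol(b1), 1)
  # df = 1 column is the linear term up to affine rescaling
  r2 <- suppressWarnings(summary(lm(b1[, 1] ~ x))$r.squared)
  expect_equal(r2, 1, tolerance = 1e-12)

  b3 <- ncs_basis(x, df = 3)
  expect_equal(ncol(b3), 3)
  expect_equal(attr(b3, "knots"),
               quantile(x, c(1, 2) / 3, names = FALSE))

  # zero second difference beyond the boundary knots
  xx <- c(seq(-50, 0, 1), seq(100, 150, 1))
  bb <- splines::ns(xx, knots = attr(b3, "knots"),
                    Boundary.knots = attr(b3, "Boundary.knots"))
  for (j in 1:3) {
    left <- bb[xx <= 0, j]; right <- bb[xx >= 100, j]
    expect_lt(max(abs(diff(diff(left)))), 1e-9)
    expect_lt(max(abs(diff(diff(right)))), 1e-9)
  }

  # span equality with the truncated-power construction at fixed points
  pts <- c(7.3, 22.2, 48, 66.61, 93)
  ref <- natural_tp_basis(pts, attr(b3, "knots"), attr(b3, "Boundary.knots"))
  new <- splines::ns(pts, knots = attr(b3, "knots"),
                     Boundary.knots = attr(b3, "Boundary.knots"))
  for (j in seq_len(ncol(new))) {
    fit <- lm(new[, j] ~ ref)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
  for (j in seq_len(ncol(ref))) {
    fit <- lm(ref[, j] ~ new)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }

  expect_error(ncs_basis(rep(1, 10), df = 2), "distinct")
})

test_that("AIC selection prefers the generative flexibility", {
  # purely linear log-odds: df = 1 should win most replicates
  wins <- 0L
  set.seed(42)
  for (r in 1:100) {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(-0.6 + 0.9 * x))
    scr <- select_df(x, y, candidates = 1:5)
    wins <- wins + (scr$df == 1L)
  }
  expect_gt(wins, 50L)

  # single candidate returned unconditionally
  set.seed(1)
  x <- rnorm(200); y <- rbinom(200, 1, plogis(x))
  expect_equal(select_df(x, y, candidates = 3)$df, 3L)
  # AIC bookkeeping: aic = 2k - 2 loglik with k = df + intercept
  scr <- select_df(x, y, candidates = 2)
  expect_equal(scr$aic, 2 * 3 - 2 * scr$fit$loglik)
})

test_that("screening covers all nine variables, ranks true effects, and ignores order", {
  eff <- c(sofa_neuro = 0, sofa_resp = 0, sofa_renal = 0, sofa_hepatic = 0,
           sofa_coag = 0, sofa_cardio = 0, hs_ctnt_points = log(2.2),
           nt_probnp_points = 0, af = 0, hr_points = 0)
  co <- generate_cohort(generator_config(n = 2000, seed = 5,
                                         effect_log_odds = eff))
  scr <- screen_variables(co)
  expect_length(scr$results, 9)
  expect_equal(sort(names(scr$results)),
               sort(c("hs_ctnt", "nt_probnp", "hr", "sbp", "dbp", "map",
                      "pp", "rpp", "ppp")))
  expect_gt(scr$results$hs_ctnt$auc, scr$results$sbp$auc)
  expect_equal(scr$summary$variable[1], "hs_ctnt")

  perm <- as_cohort(as.data.frame(co)[sample(nrow(co)), ], label = "perm")
  scr2 <- screen_variables(perm)
  # invariant up to floating-point accumulation order (which can flip an
  # AIC near-tie between adjacent df values)
  expect_equal(scr2$summary$variable, scr$summary$variable)
  expect_lt(max(abs(scr2$summary$auc - scr$summary$auc)), 1e-3)
})

test_that("null outcomes give near-chance AUC for every screened variable", {
  eff <- c(sofa_neuro = 0, sofa_resp = 0, sofa_renal = 0, sofa_hepatic = 0,
           sofa_coag = 0, sofa_cardio = 0, hs_ctnt_points = 0,
           nt_probnp_points = 0, af = 0, hr_points = 0)
  co <- generate_cohort(generator_config(n = 10000, seed = 8,
                                         effect_log_odds = eff))
  scr <- screen_variables(co)
  expect_true(all(abs(scr$summary$auc - 0.5) < 0.05))
})

test_that("ordinalization balances log-odds increments and respects constraints", {
  set.seed(77)
  n <- 10000
  x <- rlnorm(n, log(50), 1.2)
  y <- rbinom(n, 1, plogis(-2.4 + 0.75 * (log(x) - log(50))))
  sch <- ordinalize(x, y, n_bins = 5, transform = "log", variable = "marker")

  expect_length(sch$thresholds, 4)
  expect_true(all(sch$thresholds > min(x) & sch$thresholds < max(x)))

  # monotone risk: observed mortality non-decreasing across the 5 bins
  pts <- assign_points(x, sch)
  binrate <- tapply(y, pts, mean)
  expect_length(binrate, 5)
  expect_true(all(diff(binrate) > -0.015))

  # oracle: brute-force equal-increment cuts on the true (linear-in-log)
  # model over the true lognormal distribution. Equal increments of the
  # bin-mean log-odds correspond to equal increments of truncated-normal
  # means of z = (log x - mu)/sd; solve by grid enumeration using the
  # closed-form truncated normal mean.
  tn_mean <- function(a, b) (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  zgrid <- qnorm(seq(0.04, 0.96, by = 0.04))
  combs <- t(combn(seq_along(zgrid), 4))
  best <- NULL; best_obj <- Inf
  for (i in seq_len(nrow(combs))) {
    zc <- zgrid[combs[i, ]]
    m <- tn_mean(c(-Inf, zc), c(zc, Inf))
    v <- var(diff(m))
    if (v < best_obj) { best_obj <- v; best <- zc }
  }
  oracle_logthr <- log(50) + 1.2 * best
  expect_lt(max(abs(log(sch$thresholds) - oracle_logthr)), 0.35)

  # balance: under the true model the increments of the bin-mean log-odds
  # at the estimated cut-offs are close to equal
  zc_est <- (log(sch$thresholds) - log(50)) / 1.2
  d <- diff(tn_mean(c(-Inf, zc_est), c(zc_est, Inf)))
  expect_lt(sd(d) / mean(d), 0.15)
})

test_that("two-bin ordinalization finds the separation point of separable data", {
  x <- c(seq(1, 10, length.out = 100), seq(20, 30, length.out = 100))
  y <- rep(c(0, 1), each = 100)
  sch <- ordinalize(x, y, n_bins = 2, variable = "sep")
  expect_gt(sch$thresholds, 10)
  expect_lte(sch$thresholds, 20)
  expect_error(ordinalize(rep(3, 50), rep(c(0, 1), 25), n_bins = 2), "distinct")
})

test_that("substitution models have the stated arity and null coverage", {
  co <- generate_cohort(generator_config(n = 800, seed = 15))
  sch <- point_scheme("hs_ctnt", c(15, 40, 90, 200), transform = "log")
  fit <- substitution_fit(co, sch)
  expect_length(fit$coefficients, 7)  # intercept + 5 SOFA + replacement
  expect_true("hs_ctnt_points" %in% names(fit$coefficients))
  fit_cv <- substitution_fit(co, NULL)
  expect_true("sofa_cardio" %in% names(fit_cv$coefficients))
  fit_adj <- substitution_fit(co, sch, adjust_age_sex = TRUE)
  expect_length(fit_adj$coefficients, 9)

  # all-null generator: each term's CI covers OR 1 at roughly nominal rate
  eff <- c(sofa_neuro = 0, sofa_resp = 0, sofa_renal = 0, sofa_hepatic = 0,
           sofa_coag = 0, sofa_cardio = 0, hs_ctnt_points = 0,
           nt_probnp_points = 0, af = 0, hr_points = 0)
  cover <- 0L; total <- 0L
  for (r in 1:40) {
    cfg <- generator_config(n = 600, seed = 100 + r, effect_log_odds = eff)
    cn <- generate_cohort(cfg)
    f <- substitution_fit(cn, sch)
    ci <- f$ci95[-1, , drop = FALSE]
    cover <- cover + sum(ci[, 1] <= 1 & 1 <= ci[, 2])
    total <- total + nrow(ci)
  }
  expect_gte(cover / total, 0.90)
})

test_that("extension enumeration matches the combinatorial oracle", {
  s1 <- point_scheme("hs_ctnt", c(15, 40, 90, 200), transform = "log")
  s2 <- point_scheme("nt_probnp", c(300, 1500, 5000, 15000), transform = "log")
  s3 <- point_scheme("hr", c(90, 110))
  af <- point_scheme("af_status", type = "binary")

  # three ordinal schemes, weights {1,2,3}: (3+1)^3 - 1 = 63
  m63 <- enumerate_extensions(list(a = s1, b = s2, c = s3), weights = 1:3,
                              binary_weights = 1:2)
  expect_length(m63, 63)
  expect_length(unique(vapply(m63, `[[`, character(1), "name")), 63)

  # biomarkers {1,2,3} x AF {1,2}: 4*4*3 - 1 = 47
  m47 <- enumerate_extensions(list(ctnt = s1, bnp = s2, af = af))
  expect_length(m47, 47)

  expect_length(enumerate_extensions(list(x = s1), weights = 1), 1)

  # scoring invariant: max = 24 + sum of 4w (ordinal) or 2w (binary)
  for (m in m47) {
    expect_equal(m$max_score,
                 24L + sum(vapply(m$schemes, function(s) {
                   max_base_points(s) * s$weight
                 }, integer(1))))
  }

  # deterministic ordering: single-scheme models first, lexical within
  expect_true(all(diff(vapply(m47, function(m) length(m$schemes),
                              integer(1))) >= 0))
})

test_that("selection ranks a truly better model first and clamps k", {
  wins <- 0L
  for (r in 1:100) {
    cfg <- generator_config(n = 1000, seed = 200 + r)
    co <- generate_cohort(cfg)
    sch <- generative_schemes(cfg)
    true_model <- score_model("truth", list(sch$hs_ctnt, sch$nt_probnp,
                                            point_scheme("af_status",
                                                         weight = 2,
                                                         type = "binary")))
    sel <- select_best(co, list(score_model("SOFA"), true_model), k = 10)
    wins <- wins + (sel$ranking$name[1] == "truth")
    if (r == 1) {
      # k was clamped to the candidate count; both rows carry comparisons
      expect_false(any(is.na(sel$ranking$delong_p)))
    }
  }
  expect_gte(wins, 95L)
})
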