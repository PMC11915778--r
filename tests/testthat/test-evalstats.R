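test_that("logistic MLE matches closed forms", {
  # saturated 2x2: exposed 10 events / 10 non, unexposed 5 events / 20 non
  x <- rep(c(1, 0), c(20, 25))
  y <- c(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(5, 20)))
  fit <- fit_logistic(cbind(exposed = x), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$odds_ratios["exposed"]), (10 * 20) / (10 * 5),
               tolerance = 1e-8)

  # intercept-only, 31 events of 100
  fit0 <- fit_logistic(matrix(nrow = 100, ncol = 0), rep(c(1, 0), c(31, 69)))
  expect_equal(unname(fit0$coefficients[1]), log(31 / 69), tolerance = 1e-8)
  # AIC identity
  expect_equal(fit0$aic, 2 * 1 - 2 * fit0$loglik)

  expect_error(fit_logistic(cbind(x, x), y), "rank deficient")
  expect_error(fit_logistic(cbind(x), rep(1, 45)), "both outcome classes")
})

test_that("logistic deviance is non-increasing across IRLS iterations and Wald CIs cover", {
  set.seed(99)
  cover <- 0L
  for (i in 1:100) {
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(-0.5 + 0.6 * x))
    fit <- fit_logistic(cbind(x = x), y)
    expect_true(all(diff(fit$deviance_trace) <= 1e-9))
    ci <- log(fit$ci95["x", ])
    cover <- cover + (ci[1] <= 0.6 && 0.6 <= ci[2])
  }
  # nominal 95% coverage; 99% binomial band around 95/100
  expect_gte(cover, 88L)
  expect_lte(cover, 100L)
})

test_that("AUC estimator handles separation, ties, and matches pair counting", {
  expect_equal(auc_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc_ci(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    sc <- sample(1:8, n, replace = TRUE)  # heavy ties
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_ci(sc, lab)$auc, auc_brute(sc, lab), tolerance = 1e-12)
  }
})

test_that("DeLong comparison is degenerate on identical scores and antisymmetric", {
  set.seed(8)
  s <- rnorm(60); lab <- rbinom(60, 1, 0.4)
  d0 <- delong_test(s, s, lab)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  expect_true(d0$degenerate)

  s2 <- rnorm(60)
  d12 <- delong_test(s, s2, lab)
  d21 <- delong_test(s2, s, lab)
  expect_equal(d12$z, -d21$z, tolerance = 1e-12)
  expect_equal(d12$p, d21$p, tolerance = 1e-12)
})

test_that("DeLong variance agrees with a bootstrap oracle", {
  set.seed(31)
  lab <- rep(c(1, 0), c(12, 18))
  latent <- rnorm(30, mean = lab)
  a <- latent + rnorm(30, sd = 0.8)
  b <- latent + rnorm(30, sd = 0.8)
  dl <- delong_test(a, b, lab)
  boot <- replicate(1e4, {
    i <- sample(30, replace = TRUE)
    if (length(unique(lab[i])) < 2) return(NA_real_)
    auc_ci(a[i], lab[i])$auc - auc_ci(b[i], lab[i])$auc
  })
  expect_equal(dl$var_diff, var(boot, na.rm = TRUE), tolerance = 0.15)
})

test_that("category-free NRI matches hand computation and its identities", {
  p <- runif(20)
  r0 <- nri(p, p, rep(c(0, 1), 10))
  expect_equal(r0$nri, 0)

  # every event raised, every nonevent lowered -> maximal NRI of 2
  lab <- rep(c(1, 0), c(8, 12))
  p_old <- rep(0.5, 20)
  p_new <- ifelse(lab == 1, 0.9, 0.1)
  expect_equal(nri(p_old, p_new, lab)$nri, 2)

  # 4 events (3 up, 1 down), 6 nonevents (2 up, 4 down):
  # (3-1)/4 + (4-2)/6 = 0.5 + 1/3
  lab <- rep(c(1, 0), c(4, 6))
  p_old <- rep(0.5, 10)
  p_new <- c(0.6, 0.7, 0.8, 0.4,   0.6, 0.7, 0.3, 0.2, 0.1, 0.05)
  r <- nri(p_old, p_new, lab)
  expect_equal(r$nri, 0.5 + 1 / 3, tolerance = 1e-12)
  expect_equal(r$event_component + r$nonevent_component, r$nri)
  expect_error(nri(c(0.5, 1.5), c(0.5, 0.5), c(0, 1)), "\\[0,1\\]")
})

test_that("Hosmer-Lemeshow is zero on perfectly calibrated groups and uses g-2 df", {
  # five risk levels, each with observed proportion exactly equal to p
  p <- rep(c(0.1, 0.2, 0.4, 0.6, 0.8), each = 10)
  y <- unlist(lapply(c(0.1, 0.2, 0.4, 0.6, 0.8),
                     function(q) rep(c(1, 0), c(q * 10, 10 - q * 10))))
  hl <- hosmer_lemeshow(p, y, n_groups = 5)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$df, 3L)
  expect_equal(sum(hl$groups$count), 50)
  expect_equal(hl$groups$observed_proportion, hl$groups$mean_predicted)
})

test_that("statistics are invariant to monotone score transforms and record order", {
  set.seed(13)
  n <- 150
  lab <- rbinom(n, 1, 0.3)
  a <- rnorm(n, mean = 0.8 * lab)
  b <- rnorm(n, mean = 0.5 * lab)
  mono <- function(s) exp(s / 2) + 3

  expect_equal(auc_ci(mono(a), lab)$auc, auc_ci(a, lab)$auc)
  d1 <- delong_test(a, b, lab)
  d2 <- delong_test(mono(a), mono(b), lab)
  expect_equal(d1$z, d2$z, tolerance = 1e-12)

  pa <- plogis(a); pb <- plogis(b)
  sq <- function(p) p^2  # monotone [0,1] -> [0,1]
  expect_equal(nri(pa, pb, lab)$nri, nri(sq(pa), sq(pb), lab)$nri)

  perm <- sample(n)
  expect_equal(auc_ci(a[perm], lab[perm])$auc, auc_ci(a, lab)$auc)
  dp <- delong_test(a[perm], b[perm], lab[perm])
  expect_equal(dp$z, d1$z, tolerance = 1e-12)
  hl1 <- hosmer_lemeshow(pa, lab)
  hlp <- hosmer_lemeshow(pa[perm], lab[perm])
  expect_equal(hl1$statistic, hlp$statistic, tolerance = 1e-12)
})

test_that("AUC and DeLong agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  n <- 120
  lab <- rbinom(n, 1, 0.35)
  a <- rnorm(n, 0.9 * lab)
  b <- rnorm(n, 0.4 * lab)
  ra <- pROC::roc(lab, a, quiet = TRUE, direction = "<")
  expect_equal(auc_ci(a, lab)$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  ref <- pROC::roc.test(ra, pROC::roc(lab, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  dl <- delong_test(a, b, lab)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-10)
})

test_that("AUC sample size is monotone and analytic agrees with Monte-Carlo", {
  expect_error(sample_size_auc(0.74, 0.70), "auc_null")
  n_small <- sample_size_auc(0.70, 0.74, prevalence = 0.31)
  n_big <- sample_size_auc(0.70, 0.78, prevalence = 0.31)
  expect_lte(n_big, n_small)
  # a vanishing effect needs an unattainably large cohort
  expect_error(sample_size_auc(0.70, 0.7000001, prevalence = 0.31), "1e6")

  n_mc <- sample_size_auc(0.70, 0.74, prevalence = 0.31,
                          method = "montecarlo", nsim = 800, seed = 4)
  expect_lte(abs(n_small - n_mc) / n_mc, 0.10)
})
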