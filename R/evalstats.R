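#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald inference, implemented directly
#' so every quantity (log-likelihood, AIC, standard errors) is under the
#' package's control. Convergence is declared when the maximum absolute
#' component of the score vector falls below \code{tol}; Fisher scoring steps
#' are halved whenever a step would increase the deviance, so the deviance
#' is non-increasing across iterations.
#'
#' @param x design matrix (without intercept unless \code{intercept = FALSE}).
#' @param y 0/1 outcome vector.
#' @param intercept prepend an intercept column (default \code{TRUE}).
#' @param tol convergence tolerance on the score norm (default \code{1e-8}).
#' @param max_iter iteration cap (default 100).
#' @return object of class \code{logistic_fit}: \code{coefficients},
#'   \code{se}, \code{odds_ratios}, \code{ci95} (matrix, columns lower/upper,
#'   odds-ratio scale), \code{p_values}, \code{loglik}, \code{aic},
#'   \code{deviance_trace}, \code{fitted}, \code{converged},
#'   \code{separation}.
#' @export
fit_logistic <- function(x, y, intercept = TRUE, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both outcome classes required", call. = FALSE)
  if (intercept) {
    x <- cbind("(Intercept)" = 1, x)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("design matrix is rank deficient (rank ", qrx$rank, " < ", ncol(x), ")",
         call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  beta <- numeric(k)
  dev <- function(b) {
    eta <- drop(x %*% b)
    -2 * sum(y * eta - log1p(exp(eta)))
  }
  d_old <- dev(beta)
  trace <- d_old
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(x, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: guarantees monotone deviance
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      d_new <- dev(cand)
      if (is.finite(d_new) && d_new <= d_old + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; d_new <- d_old; break }
    }
    beta <- cand
    d_old <- d_new
    trace <- c(trace, d_new)
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(x, x * w)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(diag(vcov))
  # crude but effective separation flag: runaway coefficients or vanishing
  # curvature in some direction
  separation <- any(abs(beta) > 15) || any(!is.finite(se)) || any(se > 100)
  if (separation) {
    se[abs(beta) > 15 | !is.finite(se) | se > 100] <- Inf
  }
  zq <- stats::qnorm(0.975)
  ci <- cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  loglik <- -d_old / 2
  fit <- structure(list(
    coefficients = stats::setNames(beta, colnames(x)),
    se = stats::setNames(se, colnames(x)),
    odds_ratios = stats::setNames(exp(beta), colnames(x)),
    ci95 = ci,
    p_values = stats::setNames(2 * stats::pnorm(-abs(beta / se)), colnames(x)),
    loglik = loglik,
    aic = 2 * k - 2 * loglik,
    deviance_trace = trace,
    fitted = mu,
    linear_predictor = eta,
    vcov = vcov,
    converged = converged,
    separation = separation,
    n = n
  ), class = "logistic_fit")
  fit
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f, AIC = %.2f%s)\n",
              x$n, x$loglik, x$aic,
              if (!x$converged) ", NOT CONVERGED"
              else if (x$separation) ", separation suspected" else ""))
  tab <- data.frame(
    OR = sprintf("%.3f", x$odds_ratios),
    `95% CI` = sprintf("%.3f-%.3f", x$ci95[, "lower"], x$ci95[, "upper"]),
    p = format.pval(x$p_values, digits = 3),
    check.names = FALSE
  )
  rownames(tab) <- names(x$coefficients)
  print(tab)
  invisible(x)
}

# DeLong structural components (placement values) for one score vector.
# Returns the midrank AUC and the per-observation components V10 (events)
# and V01 (non-events).
.delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  ev <- scores[labels == 1]
  ne <- scores[labels == 0]
  m <- length(ev); n <- length(ne)
  if (m == 0 || n == 0) stop("both outcome classes required", call. = FALSE)
  r_all <- rank(c(ev, ne), ties.method = "average")
  r_ev <- rank(ev, ties.method = "average")
  r_ne <- rank(ne, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_ev) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ne) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong confidence interval
#'
#' Mann-Whitney estimate of the area under the ROC curve — the probability
#' that a randomly chosen event outranks a randomly chosen non-event, ties
#' counting one half — with a Wald confidence interval from the DeLong
#' structural-component variance.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param labels 0/1 outcome.
#' @param conf confidence level (default 0.95).
#' @return list: \code{auc}, \code{se}, \code{ci} (clipped to [0,1]),
#'   \code{n_events}, \code{n_nonevents}.
#' @export
auc_ci <- function(scores, labels, conf = 0.95) {
  cmp <- .delong_components(scores, labels)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, cmp$auc + c(-1, 1) * zq * se))
  list(auc = cmp$auc, se = se, ci = ci,
       n_events = cmp$m, n_nonevents = cmp$n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores measured on the same subjects using
#' the DeLong covariance of structural components, with a two-sided normal
#' p-value. If the two score vectors induce identical placements the
#' variance of the difference is zero; the comparison is then flagged
#' degenerate with \code{z = 0, p = 1}.
#'
#' @param scores_a,scores_b two score vectors on the same subjects.
#' @param labels shared 0/1 outcome.
#' @return object of class \code{roc_comparison}: \code{auc_a}, \code{auc_b},
#'   \code{var_diff}, \code{z}, \code{p}, \code{degenerate}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  degenerate <- var_diff <= .Machine$double.eps
  z <- if (degenerate) 0 else (ca$auc - cb$auc) / sqrt(var_diff)
  structure(list(
    auc_a = ca$auc, auc_b = cb$auc,
    var_diff = var_diff, z = z,
    p = if (degenerate) 1 else 2 * stats::pnorm(-abs(z)),
    degenerate = degenerate,
    n_events = ca$m, n_nonevents = ca$n
  ), class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.4f vs %.4f (z = %.3f, p = %s%s)\n",
              x$auc_a, x$auc_b, x$z, format.pval(x$p, digits = 3),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Category-free net reclassification improvement
#'
#' Continuous NRI of a new risk model against an old one: the event
#' component is the net fraction of events whose predicted risk rose, the
#' non-event component the net fraction of non-events whose risk fell; any
#' strict change in predicted probability counts. The z statistic uses the
#' standard asymptotic variance of the two components.
#'
#' @param p_old,p_new predicted probabilities under the old and new model.
#' @param labels 0/1 outcome.
#' @param thresholds optional ascending risk-category boundaries; when given,
#'   the categorical NRI (movement between categories) is computed instead.
#' @return object of class \code{nri_result}: \code{event_component},
#'   \code{nonevent_component}, \code{nri}, \code{z}, \code{p}.
#' @export
nri <- function(p_old, p_new, labels, thresholds = NULL) {
  stopifnot(length(p_old) == length(p_new), length(p_old) == length(labels))
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1)) {
    stop("predicted probabilities must lie in [0,1]", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both outcome classes required", call. = FALSE)
  if (!is.null(thresholds)) {
    co <- findInterval(p_old, sort(thresholds))
    cn <- findInterval(p_new, sort(thresholds))
    up <- cn > co; down <- cn < co
  } else {
    up <- p_new > p_old; down <- p_new < p_old
  }
  ev <- labels == 1
  n_e <- sum(ev); n_ne <- sum(!ev)
  pu_e <- mean(up[ev]);  pd_e <- mean(down[ev])
  pu_n <- mean(up[!ev]); pd_n <- mean(down[!ev])
  event_component <- pu_e - pd_e
  nonevent_component <- pd_n - pu_n
  total <- event_component + nonevent_component
  v <- (pu_e + pd_e - event_component^2) / n_e +
       (pu_n + pd_n - nonevent_component^2) / n_ne
  z <- if (v > 0) total / sqrt(v) else 0
  structure(list(
    event_component = event_component,
    nonevent_component = nonevent_component,
    nri = total,
    z = z,
    p = if (v > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(total == 0),
    n_events = n_e, n_nonevents = n_ne,
    categorical = !is.null(thresholds)
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("%s NRI = %.4f (events %.4f + non-events %.4f), z = %.3f, p = %s\n",
              if (x$categorical) "Categorical" else "Category-free",
              x$nri, x$event_component, x$nonevent_component, x$z,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups subjects by quantiles of predicted probability (quintiles by
#' default, matching calibration-by-quintile reporting) and compares
#' observed with expected event counts:
#' \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / (n_g \bar\pi_g (1 - \bar\pi_g))}
#' on \code{n_groups - 2} degrees of freedom. Tied probabilities at a
#' quantile boundary are collapsed into the lower group; groups emptied by
#' tie collapsing are merged with a warning.
#'
#' @param p_pred predicted event probabilities.
#' @param y 0/1 outcome.
#' @param n_groups number of risk groups (default 5).
#' @return object of class \code{calibration_result}: per-group table
#'   (\code{mean_predicted}, \code{observed_proportion}, \code{events},
#'   \code{count}, \code{ci_lower}, \code{ci_upper}), \code{statistic},
#'   \code{df}, \code{p}.
#' @export
hosmer_lemeshow <- function(p_pred, y, n_groups = 5L) {
  stopifnot(length(p_pred) == length(y))
  n <- length(y)
  if (n < 2 * n_groups) stop("need at least 2 observations per group", call. = FALSE)
  qs <- stats::quantile(p_pred, probs = seq_len(n_groups - 1) / n_groups,
                        type = 7)
  # left-closed grouping, boundary ties fall in the lower group
  grp <- findInterval(p_pred, unique(qs), left.open = TRUE) + 1L
  counts <- tabulate(grp, nbins = max(grp))
  if (any(counts == 0)) {
    warning("empty calibration group after tie collapsing; groups merged")
    grp <- match(grp, sort(unique(grp)))
  }
  g <- sort(unique(grp))
  if (length(g) < length(unique(qs)) + 1) {
    warning("tied predicted probabilities collapsed ",
            n_groups - length(g), " group(s)")
  }
  obs <- tapply(y, grp, sum)
  ng <- tapply(y, grp, length)
  pbar <- tapply(p_pred, grp, mean)
  expd <- ng * pbar
  denom <- ng * pbar * (1 - pbar)
  stat <- sum((obs - expd)^2 / denom)
  df <- length(g) - 2L
  cis <- t(vapply(seq_along(g), function(i) {
    stats::binom.test(obs[[i]], ng[[i]])$conf.int
  }, numeric(2)))
  structure(list(
    groups = data.frame(
      group = g,
      count = as.integer(ng),
      events = as.integer(obs),
      mean_predicted = as.numeric(pbar),
      observed_proportion = as.numeric(obs / ng),
      ci_lower = cis[, 1], ci_upper = cis[, 2]
    ),
    statistic = stat,
    df = df,
    p = stats::pchisq(stat, df = df, lower.tail = FALSE)
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi-square = %.3f, df = %d, p = %s\n",
              x$statistic, x$df, format.pval(x$p, digits = 3)))
  print(x$groups, row.names = FALSE, digits = 3)
  invisible(x)
}

# Hanley-McNeil variance of an empirical AUC with m events / n non-events.
.hanley_mcneil_var <- function(auc, m, n) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (m - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) / (m * n)
}

#' Sample size for detecting an AUC above a null value
#'
#' Smallest total n such that a two-sided z-test of the empirical AUC
#' against \code{auc_null} attains the requested power when the true AUC is
#' \code{auc_alt}. The analytic method uses the Hanley-McNeil variance under
#' the null and the alternative; the Monte-Carlo method estimates power by
#' simulating binormal scores at the alternative AUC and applying the same
#' test, searching n by bisection.
#'
#' @param auc_null null AUC (\code{>= 0.5}).
#' @param auc_alt alternative AUC (\code{> auc_null}).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param prevalence event fraction of the cohort (default 0.31).
#' @param method \code{"analytic"} or \code{"montecarlo"}.
#' @param nsim simulation replicates per candidate n (Monte-Carlo method).
#' @param seed seed for the Monte-Carlo search.
#' @return required total sample size (integer).
#' @export
sample_size_auc <- function(auc_null, auc_alt, alpha = 0.05, power = 0.80,
                            prevalence = 0.31,
                            method = c("analytic", "montecarlo"),
                            nsim = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1)) {
    stop("need 0.5 <= auc_null < auc_alt < 1", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            prevalence > 0, prevalence < 1)
  za <- stats::qnorm(1 - alpha / 2)
  if (method == "analytic") {
    analytic_power <- function(n) {
      m <- max(2, round(prevalence * n)); nn <- n - m
      if (nn < 2) return(0)
      v0 <- .hanley_mcneil_var(auc_null, m, nn)
      v1 <- .hanley_mcneil_var(auc_alt, m, nn)
      stats::pnorm((auc_alt - auc_null - za * sqrt(v0)) / sqrt(v1))
    }
    n <- 8L
    while (analytic_power(n) < power) {
      n <- n + 1L
      if (n > 1e6) stop("required n exceeds 1e6; effect too small", call. = FALSE)
    }
    return(n)
  }
  # Monte-Carlo: binormal scores, events shifted so the true AUC is auc_alt
  mc_power <- function(n) {
    m <- max(2, round(prevalence * n)); nn <- n - m
    delta <- sqrt(2) * stats::qnorm(auc_alt)
    rej <- vapply(seq_len(nsim), function(i) {
      sc <- c(stats::rnorm(m, delta), stats::rnorm(nn))
      lab <- rep(c(1, 0), c(m, nn))
      cmp <- .delong_components(sc, lab)
      v0 <- .hanley_mcneil_var(auc_null, m, nn)
      abs(cmp$auc - auc_null) / sqrt(v0) > za
    }, logical(1))
    mean(rej)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  lo <- 8L; hi <- 64L
  while (mc_power(hi) < power) {
    lo <- hi; hi <- hi * 2L
    if (hi > 1e6) stop("required n exceeds 1e6; effect too small", call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (mc_power(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Empirical type-I error of the paired DeLong test
#'
#' Simulates a null of equal discrimination: per replicate, outcome labels
#' at the given prevalence and two scores built as a shared latent predictor
#' (shifted in events) plus independent equal-variance noise, so both scores
#' have identical true AUC. Reports the fraction of two-sided DeLong tests
#' rejecting at \code{alpha}, which should approximate \code{alpha}.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n subjects per cohort.
#' @param prevalence event fraction.
#' @param alpha nominal significance level.
#' @param seed integer seed.
#' @param signal latent event/non-event shift (discrimination strength).
#' @param noise_sd standard deviation of the per-score noise.
#' @return list: \code{rejection_rate}, \code{rejections},
#'   \code{n_replicates}.
#' @export
delong_type1_sim <- function(n_replicates = 2000L, n = 250L,
                             prevalence = 0.3, alpha = 0.05, seed = 1L,
                             signal = 1, noise_sd = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  m <- round(prevalence * n)
  labels <- rep(c(1L, 0L), c(m, n - m))
  rej <- vapply(seq_len(n_replicates), function(r) {
    latent <- stats::rnorm(n, mean = signal * labels)
    a <- latent + stats::rnorm(n, sd = noise_sd)
    b <- latent + stats::rnorm(n, sd = noise_sd)
    delong_test(a, b, labels)$p < alpha
  }, logical(1))
  list(rejection_rate = mean(rej), rejections = sum(rej),
       n_replicates = n_replicates)
}
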