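#' Natural cubic spline basis
#'
#' Basis with boundary knots at the data extremes and interior knots at the
#' equally spaced quantiles implied by the degrees of freedom (df - 1
#' interior knots at probabilities 1/df, ..., (df-1)/df), so the fitted
#' function space is linear beyond the boundary knots. \code{df = 1} gives a
#' single column spanning the linear term.
#'
#' @param x points at which to evaluate the basis.
#' @param df degrees of freedom (number of basis columns), >= 1.
#' @param data values whose quantiles place the knots (defaults to \code{x}).
#' @return matrix with \code{df} columns; attributes \code{knots} and
#'   \code{Boundary.knots} allow re-evaluation at new points.
#' @export
ncs_basis <- function(x, df, data = x) {
  df <- as.integer(df)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  ux <- unique(data[is.finite(data)])
  if (length(ux) < df + 2) {
    stop("need at least df + 2 distinct values to place knots", call. = FALSE)
  }
  bk <- range(data)
  ik <- if (df > 1) {
    stats::quantile(data, probs = seq_len(df - 1) / df, names = FALSE, type = 7)
  } else numeric(0)
  b <- splines::ns(x, knots = ik, Boundary.knots = bk)
  attr(b, "class") <- "matrix"
  structure(b[, , drop = FALSE], knots = ik, Boundary.knots = bk)
}

#' Select spline flexibility by AIC
#'
#' Fits a logistic model of a binary outcome on the natural-cubic-spline
#' basis of \code{x} for each candidate df and returns the screen result of
#' the AIC minimiser (\code{AIC = 2k - 2 logLik}, k counting the intercept),
#' with ties broken toward the smaller df. The result carries a
#' \code{risk(newx)} function evaluating the fitted event probability.
#'
#' @param x continuous predictor (already on its modelling scale).
#' @param y 0/1 outcome.
#' @param candidates integer vector of df values to try (default 1..5).
#' @param variable optional variable name carried into the result.
#' @return object of class \code{spline_screen}: \code{variable}, \code{df},
#'   \code{knots}, \code{boundary_knots}, \code{aic}, \code{aic_by_df},
#'   \code{auc}, \code{auc_ci}, \code{risk}, \code{linear_predictor},
#'   \code{fit}.
#' @export
select_df <- function(x, y, candidates = 1:5, variable = NULL) {
  if (length(candidates) < 1) stop("no candidate df values", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  fits <- lapply(candidates, function(df) {
    tryCatch({
      b <- ncs_basis(x, df)
      list(df = df, basis = b, fit = fit_logistic(b, y))
    }, error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("spline fit failed for every candidate df", call. = FALSE)
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$fit$aic, numeric(1))
  best <- fits[[which.min(aics)]]  # which.min takes the first = smallest df
  ik <- attr(best$basis, "knots"); bk <- attr(best$basis, "Boundary.knots")
  beta <- best$fit$coefficients
  risk <- function(newx) {
    b <- splines::ns(newx, knots = ik, Boundary.knots = bk)
    stats::plogis(drop(cbind(1, b) %*% beta))
  }
  a <- auc_ci(best$fit$fitted, y)
  structure(list(
    variable = variable, df = best$df,
    knots = ik, boundary_knots = bk,
    aic = best$fit$aic,
    aic_by_df = stats::setNames(aics, vapply(fits, `[[`, integer(1), "df")),
    auc = a$auc, auc_ci = a$ci,
    risk = risk,
    linear_predictor = best$fit$linear_predictor,
    fit = best$fit
  ), class = "spline_screen")
}

#' @export
print.spline_screen <- function(x, ...) {
  cat(sprintf("<spline_screen %s: df = %d, AIC = %.2f, AUC = %.3f (%.3f-%.3f)>\n",
              x$variable %||% "?", x$df, x$aic, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

# The nine continuous cardiovascular candidates, with their modelling scale.
.screen_variables <- c(hs_ctnt = "log", nt_probnp = "log", hr = "identity",
                       sbp = "identity", dbp = "identity", map = "identity",
                       pp = "identity", rpp = "identity", ppp = "identity")

#' Spline screening of cardiovascular variables
#'
#' Screens continuous cardiovascular variables for association with 30-day
#' mortality: each is modelled with a natural cubic spline logistic fit at
#' the AIC-selected flexibility and summarised by the AUC of its fitted
#' risk. The right-skewed biomarkers hs-cTnT and NT-proBNP enter on the log
#' scale; derived hemodynamics (MAP, PP, RPP, PPP) are computed on the fly.
#' Fit failures are reported per variable without aborting the rest.
#'
#' @param cohort a \code{ce_cohort}.
#' @param variables named character vector mapping variable name to
#'   transform (\code{"identity"}/\code{"log"}); defaults to the nine
#'   standard candidates.
#' @param df_candidates df values for AIC selection.
#' @return object of class \code{screen_result}: a list of
#'   \code{spline_screen} per variable (or a \code{variable}/\code{error}
#'   stub on failure), plus a \code{summary} data.frame sorted by AUC.
#' @export
screen_variables <- function(cohort, variables = .screen_variables,
                             df_candidates = 1:5) {
  y <- cohort$died_30d
  results <- lapply(names(variables), function(v) {
    tryCatch({
      raw <- .scheme_values(cohort, v)
      xt <- if (variables[[v]] == "log") log(raw) else raw
      scr <- select_df(xt, y, df_candidates, variable = v)
      scr$log_transformed <- variables[[v]] == "log"
      scr
    }, error = function(e) {
      structure(list(variable = v, error = conditionMessage(e)),
                class = "spline_screen_error")
    })
  })
  names(results) <- names(variables)
  ok <- !vapply(results, inherits, logical(1), "spline_screen_error")
  summary <- data.frame(
    variable = names(variables)[ok],
    transform = unname(variables[ok]),
    df = vapply(results[ok], `[[`, integer(1), "df"),
    aic = vapply(results[ok], `[[`, numeric(1), "aic"),
    auc = vapply(results[ok], `[[`, numeric(1), "auc"),
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-summary$auc), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Spline screening of cardiovascular variables (sorted by AUC):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  errs <- Filter(function(r) inherits(r, "spline_screen_error"), x$results)
  for (e in errs) cat(sprintf("  %s: FAILED (%s)\n", e$variable, e$error))
  invisible(x)
}

#' Ordinalize a continuous variable into balanced-effect point groups
#'
#' Converts a continuous predictor into an ordinal point group (0 to
#' \code{n_bins - 1} points) with cut-offs positioned so the effect size is
#' balanced across categories: the mean spline-fitted log-odds of the bins
#' should rise by approximately equal increments from bin to bin.
#'
#' The estimator fits the AIC-selected spline risk model, initialises the
#' \code{n_bins - 1} thresholds at equal quantiles, and runs a coordinate
#' descent over a quantile grid (steps of \code{grid_step}, default 0.5% of
#' the data) minimising the variance of adjacent-bin increments of the mean
#' fitted log-odds, subject to every bin retaining at least \code{min_mass}
#' of the observations. Exact ties in the objective are broken toward the
#' larger first-to-last log-odds span (which also makes the two-bin case,
#' where the variance of a single increment is vacuously zero, pick the
#' point of maximal separation).
#'
#' @param x continuous predictor values (original units).
#' @param y 0/1 outcome.
#' @param n_bins number of point groups (default 5, giving 0-4 points).
#' @param transform \code{"identity"} or \code{"log"}: modelling scale.
#' @param grid_step quantile grid resolution for candidate thresholds.
#' @param min_mass minimum fraction of observations per bin.
#' @param df_candidates spline df candidates for the risk fit.
#' @param variable variable name stored in the returned scheme.
#' @param max_sweeps coordinate-descent sweep cap.
#' @return a \code{point_scheme} (weight 1) whose thresholds are in original
#'   units and lie inside the observed data range; attributes
#'   \code{bin_logodds} (achieved mean fitted log-odds per bin),
#'   \code{objective} (final increment variance) and \code{screen} (the
#'   underlying \code{spline_screen}).
#' @export
ordinalize <- function(x, y, n_bins = 5L, transform = c("identity", "log"),
                       grid_step = 0.005, min_mass = 0.05,
                       df_candidates = 1:5, variable = "x",
                       max_sweeps = 30L) {
  transform <- match.arg(transform)
  n <- length(x)
  stopifnot(length(y) == n, n_bins >= 2)
  if (length(unique(x)) < n_bins) stop("x has fewer distinct values than bins",
                                       call. = FALSE)
  xt <- if (transform == "log") log(x) else x
  scr <- select_df(xt, y, df_candidates, variable = variable)
  lp <- scr$linear_predictor
  ord <- order(xt)
  xs <- xt[ord]
  cs <- cumsum(lp[ord])
  k <- n_bins - 1L
  min_gap <- max(1L, ceiling(min_mass * n))
  # candidate cut positions: i means "i observations below the threshold";
  # only positions where the next value strictly increases give a valid
  # (strictly increasing, left-closed) threshold
  grid <- unique(round(n * seq(grid_step, 1 - grid_step, by = grid_step)))
  grid <- grid[grid >= 1 & grid <= n - 1]
  grid <- grid[xs[grid + 1] > xs[grid]]
  if (length(grid) < k) stop("too few distinct cut positions; x too discrete",
                             call. = FALSE)
  objective <- function(cuts) {
    edges <- c(0L, cuts, n)
    counts <- diff(edges)
    if (any(counts < min_gap)) return(c(Inf, -Inf))
    sums <- diff(c(0, cs[edges[-1]]))
    means <- sums / counts
    d <- diff(means)
    v <- if (length(d) > 1) stats::var(d) else 0
    c(v, means[length(means)] - means[1])
  }
  cuts <- grid[vapply(seq_len(k) / n_bins, function(p) {
    which.min(abs(grid - p * n))
  }, integer(1))]
  if (anyDuplicated(cuts)) cuts <- grid[round(seq(1, length(grid), length.out = k))]
  cur <- objective(cuts)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      lo <- if (j > 1) cuts[j - 1] + min_gap else min_gap
      hi <- if (j < k) cuts[j + 1] - min_gap else n - min_gap
      cand <- grid[grid >= lo & grid <= hi]
      if (length(cand) == 0) next
      vals <- vapply(cand, function(c_j) {
        cc <- cuts; cc[j] <- c_j; objective(cc)
      }, numeric(2))
      # lexicographic: minimise increment variance, then maximise span
      best <- order(vals[1, ], -vals[2, ])[1]
      if (cand[best] != cuts[j] &&
          (vals[1, best] < cur[1] - 1e-15 ||
           (vals[1, best] <= cur[1] + 1e-15 && vals[2, best] > cur[2] + 1e-15))) {
        cuts[j] <- cand[best]
        cur <- objective(cuts)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!is.finite(cur[1])) stop("no threshold configuration satisfies the bin-mass constraint",
                               call. = FALSE)
  thr_t <- xs[cuts + 1]
  thresholds <- if (transform == "log") exp(thr_t) else thr_t
  edges <- c(0L, cuts, n)
  bin_logodds <- diff(c(0, cs[edges[-1]])) / diff(edges)
  scheme <- point_scheme(variable, thresholds, weight = 1L, transform = transform)
  attr(scheme, "bin_logodds") <- as.numeric(bin_logodds)
  attr(scheme, "objective") <- cur[1]
  attr(scheme, "screen") <- scr
  scheme
}

#' Component-substitution multivariable model
#'
#' Multivariable logistic model of 30-day mortality on the five
#' non-cardiovascular SOFA sub-scores plus either the cardiovascular
#' sub-score itself (\code{replacement = NULL}) or a replacement point
#' group. Ordinal replacement schemes enter as their point values; a binary
#' AF scheme enters as the presence indicator (so its odds ratio is per
#' presence). Optional age/sex adjustment is available. Separation is
#' flagged on the fit and the affected confidence bounds reported as
#' unbounded.
#'
#' @param cohort a \code{ce_cohort}.
#' @param replacement \code{NULL} or a \code{point_scheme}.
#' @param adjust_age_sex also include age and sex (default \code{FALSE}).
#' @return a \code{logistic_fit}; the replacement term is named
#'   \code{<variable>_points} (or \code{af} for a binary scheme).
#' @export
substitution_fit <- function(cohort, replacement = NULL,
                             adjust_age_sex = FALSE) {
  x <- cbind(
    sofa_neuro = cohort$sofa_neuro,
    sofa_resp = cohort$sofa_resp,
    sofa_renal = cohort$sofa_renal,
    sofa_hepatic = cohort$sofa_hepatic,
    sofa_coag = cohort$sofa_coag
  )
  if (is.null(replacement)) {
    hd <- derive_hemodynamics(cohort$sbp, cohort$dbp, cohort$hr)
    cv <- cardiovascular_sofa(hd$map, cohort$dopamine_dose,
                              cohort$norepinephrine_dose,
                              cohort$other_vasoactive == 1)
    x <- cbind(x, sofa_cardio = cv)
  } else {
    stopifnot(inherits(replacement, "point_scheme"))
    if (replacement$type == "binary") {
      x <- cbind(x, af = as.integer(cohort$af_status != "none"))
    } else {
      pts <- assign_points(.scheme_values(cohort, replacement$variable),
                           replacement)
      col <- paste0(replacement$variable, "_points")
      x <- cbind(x, pts)
      colnames(x)[ncol(x)] <- col
    }
  }
  if (adjust_age_sex) {
    x <- cbind(x, age = cohort$age, sex_male = as.integer(cohort$sex == "male"))
  }
  fit_logistic(x, cohort$died_30d)
}

#' Enumerate weighted score extensions
#'
#' All score models formed by choosing, independently per candidate scheme,
#' either absence or one of its allowed weights — excluding the empty choice
#' that would leave the base score unchanged. Ordering is deterministic:
#' by number of included schemes, then lexically by scheme names and
#' weights.
#'
#' @param base_schemes named list of weight-1 \code{point_scheme} objects.
#' @param weights allowed weights for ordinal schemes (default 1:3).
#' @param binary_weights allowed weights for binary schemes (default 1:2,
#'   i.e. single or double AF points).
#' @return list of \code{score_model} objects.
#' @export
enumerate_extensions <- function(base_schemes, weights = 1:3,
                                 binary_weights = 1:2) {
  stopifnot(length(base_schemes) >= 1)
  if (is.null(names(base_schemes))) {
    names(base_schemes) <- vapply(base_schemes, `[[`, character(1), "variable")
  }
  opts <- lapply(base_schemes, function(s) {
    c(0L, if (s$type == "binary") as.integer(binary_weights)
          else as.integer(weights))
  })
  combos <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[rowSums(combos > 0) > 0, , drop = FALSE]
  models <- lapply(seq_len(nrow(combos)), function(i) {
    w <- unlist(combos[i, ])
    inc <- which(w > 0)
    schemes <- lapply(inc, function(j) {
      s <- base_schemes[[j]]
      s$weight <- as.integer(w[j])
      s
    })
    nm <- paste0("SOFA+", paste0(names(base_schemes)[inc], "x", w[inc],
                                 collapse = "+"))
    score_model(nm, schemes)
  })
  keys <- vapply(models, function(m) {
    sprintf("%02d|%s", length(m$schemes), m$name)
  }, character(1))
  models[order(keys)]
}

#' Rank candidate extensions and pick the best
#'
#' Ranks candidate score models by training-cohort AUC (ties broken toward
#' fewer added points, then name), then compares the top \code{k} against
#' the base SOFA score with the paired DeLong test and the category-free
#' NRI. NRI probabilities come from univariate logistic recalibrations of
#' each integer score, which preserve score order.
#'
#' @param cohort training \code{ce_cohort}.
#' @param candidates list of \code{score_model} objects.
#' @param k number of top models to test against base SOFA (default 4;
#'   clamped to the candidate count).
#' @return object of class \code{model_selection}: \code{ranking}
#'   (data.frame), \code{best} (a \code{score_model}), \code{base_auc},
#'   \code{comparisons} (list of \code{roc_comparison}/\code{nri_result}
#'   pairs for the top k).
#' @export
select_best <- function(cohort, candidates, k = 4L) {
  stopifnot(length(candidates) >= 2)
  y <- cohort$died_30d
  if (length(unique(y)) < 2) stop("AUC undefined on a single-class cohort",
                                  call. = FALSE)
  base <- base_sofa(cohort)
  base_auc <- auc_ci(base, y)
  p_base <- fit_logistic(cbind(score = base), y)$fitted
  scores <- lapply(candidates, function(m) composite_score(cohort, m))
  aucs <- lapply(scores, auc_ci, labels = y)
  ranking <- data.frame(
    name = vapply(candidates, `[[`, character(1), "name"),
    auc = vapply(aucs, `[[`, numeric(1), "auc"),
    auc_lo = vapply(aucs, function(a) a$ci[1], numeric(1)),
    auc_hi = vapply(aucs, function(a) a$ci[2], numeric(1)),
    added_max = vapply(candidates, function(m) m$max_score - 24L, integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-ranking$auc, ranking$added_max, ranking$name)
  ranking <- ranking[ord, ]
  candidates <- candidates[ord]
  scores <- scores[ord]
  rownames(ranking) <- NULL
  k <- min(as.integer(k), length(candidates))
  ranking$delong_p <- NA_real_
  ranking$nri <- NA_real_
  ranking$nri_p <- NA_real_
  comparisons <- vector("list", k)
  for (i in seq_len(k)) {
    dl <- delong_test(scores[[i]], base, y)
    p_new <- fit_logistic(cbind(score = scores[[i]]), y)$fitted
    nr <- nri(p_base, p_new, y)
    ranking$delong_p[i] <- dl$p
    ranking$nri[i] <- nr$nri
    ranking$nri_p[i] <- nr$p
    comparisons[[i]] <- list(model = candidates[[i]]$name, delong = dl, nri = nr)
  }
  structure(list(ranking = ranking, best = candidates[[1]],
                 base_auc = base_auc, comparisons = comparisons),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("Base SOFA AUC %.3f (%.3f-%.3f); %d candidates ranked.\n",
              x$base_auc$auc, x$base_auc$ci[1], x$base_auc$ci[2],
              nrow(x$ranking)))
  print(utils::head(x$ranking, 8), row.names = FALSE, digits = 3)
  cat(sprintf("Selected: %s\n", x$best$name))
  invisible(x)
}

#' Full derivation pipeline on a training cohort
#'
#' Runs the four derivation stages on a training cohort: (1) spline
#' screening of the nine continuous cardiovascular variables and
#' ordinalization of hs-cTnT, NT-proBNP (five bins, log scale) and heart
#' rate (three bins) plus the binary AF scheme; (2) component-substitution
#' multivariable models for each point group; (3) retention of point groups
#' independently and positively associated with mortality (Wald p below
#' \code{retain_alpha} and odds ratio above 1), enumeration of all weighted
#' extensions of the retained schemes, and AUC ranking with DeLong/NRI
#' comparison of the top \code{k} against the base SOFA score.
#'
#' @param train training \code{ce_cohort}.
#' @param df_candidates spline df candidates.
#' @param weights,binary_weights allowed weights (see
#'   \code{\link{enumerate_extensions}}).
#' @param k top models to compare against base SOFA.
#' @param retain_alpha significance level for retaining a point group.
#' @return object of class \code{derivation_report}: \code{screen},
#'   \code{schemes}, \code{substitution} (list of \code{logistic_fit}),
#'   \code{retained}, \code{selection} (a \code{model_selection}),
#'   \code{model} (the selected \code{score_model}).
#' @export
derive_extension <- function(train, df_candidates = 1:5, weights = 1:3,
                             binary_weights = 1:2, k = 4L,
                             retain_alpha = 0.05) {
  screen <- screen_variables(train, df_candidates = df_candidates)
  y <- train$died_30d
  schemes <- list(
    hs_ctnt = ordinalize(train$hs_ctnt, y, n_bins = 5, transform = "log",
                         df_candidates = df_candidates, variable = "hs_ctnt"),
    nt_probnp = ordinalize(train$nt_probnp, y, n_bins = 5, transform = "log",
                           df_candidates = df_candidates,
                           variable = "nt_probnp"),
    hr = ordinalize(train$hr, y, n_bins = 3, transform = "identity",
                    df_candidates = df_candidates, variable = "hr"),
    af = point_scheme("af_status", weight = 1L, type = "binary")
  )
  substitution <- c(
    list(cardiovascular = substitution_fit(train, NULL)),
    lapply(schemes, function(s) substitution_fit(train, s))
  )
  term_of <- function(s) if (s$type == "binary") "af"
                         else paste0(s$variable, "_points")
  retained <- vapply(schemes, function(s) {
    f <- substitution[[if (s$type == "binary") "af" else s$variable]]
    tm <- term_of(s)
    is.finite(f$p_values[tm]) && f$p_values[tm] < retain_alpha &&
      f$odds_ratios[tm] > 1
  }, logical(1))
  if (!any(retained)) {
    stop("no point group is independently associated with mortality; ",
         "nothing to extend", call. = FALSE)
  }
  candidates <- enumerate_extensions(schemes[retained], weights = weights,
                                     binary_weights = binary_weights)
  selection <- select_best(train, candidates, k = k)
  structure(list(screen = screen, schemes = schemes,
                 substitution = substitution, retained = retained,
                 selection = selection, model = selection$best),
            class = "derivation_report")
}

#' @export
print.derivation_report <- function(x, ...) {
  print(x$screen)
  cat("\nRetained point groups:",
      paste(names(x$retained)[x$retained], collapse = ", "), "\n\n")
  print(x$selection)
  invisible(x)
}
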