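#' Ordinal point scheme
#'
#' Maps one variable to weighted score points. An \code{ordinal} scheme
#' carries four strictly increasing thresholds defining five bins worth
#' 0..4 base points; binning is left-closed, so a value equal to a threshold
#' enters the upper bin. A \code{binary} scheme (atrial fibrillation) awards
#' 2 base points for presence, 0 otherwise. Base points are multiplied by an
#' integer \code{weight}.
#'
#' Thresholds are stored in original variable units. The \code{transform}
#' field records the modelling scale on which the cut-offs were derived
#' (binning itself is order-preserving, so raw values can be binned
#' directly).
#'
#' @param variable variable name (a cohort column or one of \code{map},
#'   \code{pp}, \code{rpp}, \code{ppp}).
#' @param thresholds ascending numeric cut-offs (ordinal schemes);
#'   \code{NULL} for binary schemes.
#' @param weight integer point multiplier.
#' @param transform \code{"identity"} or \code{"log"}.
#' @param type \code{"ordinal"} or \code{"binary"}.
#' @return object of class \code{point_scheme}.
#' @export
point_scheme <- function(variable, thresholds = NULL, weight = 1L,
                         transform = c("identity", "log"),
                         type = c("ordinal", "binary")) {
  transform <- match.arg(transform)
  type <- match.arg(type)
  weight <- as.integer(weight)
  if (weight < 1L) stop("weight must be a positive integer", call. = FALSE)
  if (type == "ordinal") {
    if (is.null(thresholds) || length(thresholds) < 1) {
      stop("ordinal scheme requires thresholds", call. = FALSE)
    }
    thresholds <- as.numeric(thresholds)
    if (is.unsorted(thresholds, strictly = TRUE)) {
      stop("thresholds must be strictly increasing", call. = FALSE)
    }
  } else {
    thresholds <- NULL
  }
  structure(list(variable = variable, transform = transform,
                 thresholds = thresholds, weight = weight, type = type),
            class = "point_scheme")
}

#' @export
print.point_scheme <- function(x, ...) {
  if (x$type == "binary") {
    cat(sprintf("<point_scheme %s: binary, presence = %d points (weight %d)>\n",
                x$variable, 2L * x$weight, x$weight))
  } else {
    cat(sprintf("<point_scheme %s (%s): cut-offs %s, 0-%d points (weight %d)>\n",
                x$variable, x$transform,
                paste(signif(x$thresholds, 4), collapse = ", "),
                length(x$thresholds) * x$weight, x$weight))
  }
  invisible(x)
}

#' Maximum base points of a scheme
#' @param scheme a \code{point_scheme}.
#' @return integer maximum of the unweighted points (4 for a five-bin
#'   ordinal scheme, 2 for binary).
#' @export
max_base_points <- function(scheme) {
  if (scheme$type == "binary") 2L else length(scheme$thresholds)
}

#' Assign weighted points to values under a scheme
#'
#' Ordinal schemes: the bin index by left-closed thresholds
#' (\code{value < t1} gives 0, \code{value >= t4} gives 4), times the
#' weight. Binary schemes: presence (nonzero/\code{TRUE}/AF status other
#' than \code{"none"}) gives \code{2 * weight}.
#'
#' @param value numeric vector (ordinal), or presence indicator / AF status
#'   vector (binary).
#' @param scheme a \code{point_scheme}.
#' @return integer vector of weighted points.
#' @export
assign_points <- function(value, scheme) {
  if (scheme$type == "binary") {
    present <- if (is.character(value) || is.factor(value)) {
      as.character(value) != "none"
    } else {
      as.logical(value)
    }
    return(as.integer(present) * 2L * scheme$weight)
  }
  if (any(!is.finite(value))) stop("value must be finite", call. = FALSE)
  v <- if (scheme$transform == "log") log(value) else value
  th <- if (scheme$transform == "log") log(scheme$thresholds) else scheme$thresholds
  as.integer(findInterval(v, th)) * scheme$weight
}

#' Cardiovascular SOFA sub-score
#'
#' The original cardiovascular tier table: 0 when MAP >= 70 mmHg without
#' vasoactive support; 1 for MAP < 70 mmHg without support; 2 for dopamine
#' at or below 5 ug/kg/min or dobutamine at any dose
#' (\code{other_vasoactive}); 3 for dopamine above 5 or norepinephrine at
#' or below 0.1 ug/kg/min; 4 for dopamine above 15 or norepinephrine above
#' 0.1. The highest applicable tier wins. Other pressor dialects
#' (epinephrine, vasopressin) are mapped by the caller onto the
#' norepinephrine dose scale.
#'
#' @param map mean arterial pressure, mmHg.
#' @param dopamine dopamine dose, ug/kg/min (0 if none).
#' @param norepinephrine norepinephrine dose, ug/kg/min (0 if none).
#' @param other_vasoactive logical: any-dose dobutamine (or equivalent).
#' @return integer vector of sub-scores 0..4.
#' @export
cardiovascular_sofa <- function(map, dopamine = 0, norepinephrine = 0,
                                other_vasoactive = FALSE) {
  if (any(dopamine < 0) || any(norepinephrine < 0)) {
    stop("vasoactive doses must be non-negative", call. = FALSE)
  }
  n <- max(length(map), length(dopamine), length(norepinephrine),
           length(other_vasoactive))
  map <- rep_len(map, n); dopamine <- rep_len(dopamine, n)
  norepinephrine <- rep_len(norepinephrine, n)
  other_vasoactive <- rep_len(as.logical(other_vasoactive), n)
  score <- integer(n)
  score[map < 70] <- 1L
  score[(dopamine > 0 & dopamine <= 5) | other_vasoactive] <- 2L
  score[dopamine > 5 | (norepinephrine > 0 & norepinephrine <= 0.1)] <- 3L
  score[dopamine > 15 | norepinephrine > 0.1] <- 4L
  score
}

#' Total SOFA score
#'
#' Arithmetic sum of the six organ sub-scores (0-24 points).
#'
#' @param components numeric vector of six sub-scores, or a matrix/data.frame
#'   with six columns (one row per patient).
#' @return integer total(s).
#' @export
total_sofa <- function(components) {
  m <- if (is.null(dim(components))) matrix(components, nrow = 1) else
    as.matrix(components)
  if (ncol(m) != 6) stop("six SOFA sub-scores required", call. = FALSE)
  if (any(m < 0 | m > 4 | m != round(m))) {
    stop("each sub-score must be an integer in [0,4]", call. = FALSE)
  }
  as.integer(rowSums(m))
}

#' Score model: base SOFA plus weighted point schemes
#'
#' @param name model name.
#' @param schemes list of \code{point_scheme} objects (possibly empty, giving
#'   the plain SOFA score).
#' @return object of class \code{score_model} with a \code{max_score} field
#'   (24 plus the weighted scheme maxima).
#' @export
score_model <- function(name, schemes = list()) {
  stopifnot(is.list(schemes),
            all(vapply(schemes, inherits, logical(1), "point_scheme")))
  added <- if (length(schemes) == 0) 0L else
    sum(vapply(schemes, function(s) max_base_points(s) * s$weight, integer(1)))
  structure(list(name = name, schemes = schemes,
                 includes_base_sofa = TRUE,
                 max_score = 24L + added),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model '%s': SOFA + %d scheme(s), range 0-%d>\n",
              x$name, length(x$schemes), x$max_score))
  for (s in x$schemes) print(s)
  invisible(x)
}

# Extract the raw values a scheme scores from a cohort data.frame,
# computing derived hemodynamics on the fly.
.scheme_values <- function(cohort, variable) {
  if (variable %in% names(cohort)) return(cohort[[variable]])
  if (variable %in% c("map", "pp", "rpp", "ppp")) {
    hd <- derive_hemodynamics(cohort$sbp, cohort$dbp, cohort$hr)
    return(hd[[variable]])
  }
  if (variable %in% c("af", "af_status")) return(cohort$af_status)
  stop("scheme references a field absent from the cohort: ", variable,
       call. = FALSE)
}

#' Composite score under a model
#'
#' Base SOFA (five recorded sub-scores plus the cardiovascular sub-score
#' computed from MAP and vasoactive doses) plus the weighted points of every
#' scheme in the model. For the CE-SOFA composition (SOFA + hs-cTnT points +
#' NT-proBNP points + double AF points) the attainable range is 0-36.
#'
#' @param cohort a \code{ce_cohort} (or conforming data.frame).
#' @param model a \code{score_model}.
#' @param detail return the per-scheme point columns as well.
#' @return integer vector of composite scores, or (with \code{detail}) a
#'   data.frame with one column per component.
#' @export
composite_score <- function(cohort, model, detail = FALSE) {
  hd <- derive_hemodynamics(cohort$sbp, cohort$dbp, cohort$hr)
  cv <- cardiovascular_sofa(hd$map, cohort$dopamine_dose,
                            cohort$norepinephrine_dose,
                            cohort$other_vasoactive == 1)
  base <- total_sofa(cbind(cohort$sofa_neuro, cohort$sofa_resp,
                           cohort$sofa_renal, cohort$sofa_hepatic,
                           cohort$sofa_coag, cv))
  pts <- lapply(model$schemes, function(s) {
    assign_points(.scheme_values(cohort, s$variable), s)
  })
  total <- base + if (length(pts)) Reduce(`+`, pts) else 0L
  if (!detail) return(as.integer(total))
  out <- data.frame(sofa = base)
  for (i in seq_along(pts)) {
    out[[paste0(model$schemes[[i]]$variable, "_points")]] <- pts[[i]]
  }
  out$composite <- as.integer(total)
  out
}

#' Base SOFA score of a cohort
#'
#' Convenience wrapper: the six-component SOFA total with the cardiovascular
#' sub-score computed from MAP and vasoactive doses.
#'
#' @param cohort a \code{ce_cohort}.
#' @return integer vector 0-24.
#' @export
base_sofa <- function(cohort) {
  composite_score(cohort, score_model("SOFA"))
}

#' Assemble a CE-SOFA model from cut-offs
#'
#' Builds the cardiac-extended composition — SOFA plus hs-cTnT points
#' (weight 1), NT-proBNP points (weight 1) and double AF points — from
#' user-supplied or derived biomarker cut-offs. The numeric cut-offs are not
#' shipped as package constants: transcribe them from a published scheme or
#' re-derive them with \code{\link{derive_extension}}.
#'
#' @param ctnt_thresholds four ascending hs-cTnT cut-offs, ng/L.
#' @param bnp_thresholds four ascending NT-proBNP cut-offs, ng/L.
#' @param af_weight AF point multiplier (default 2: "double AF points").
#' @return a \code{score_model} with maximum score \code{24 + 4 + 4 + 2*af_weight}.
#' @export
ce_sofa_model <- function(ctnt_thresholds, bnp_thresholds, af_weight = 2L) {
  score_model("CE-SOFA", list(
    point_scheme("hs_ctnt", ctnt_thresholds, weight = 1L, transform = "log"),
    point_scheme("nt_probnp", bnp_thresholds, weight = 1L, transform = "log"),
    point_scheme("af_status", weight = af_weight, type = "binary")
  ))
}

#' Read / write a score model definition file
#'
#' Structured-text (YAML) model files carry, per scheme: variable,
#' transform, thresholds, type and weight — so a derived model can be
#' archived and re-applied to new cohorts.
#'
#' @param model a \code{score_model} (for writing).
#' @param path file path.
#' @return \code{read_score_model}: a \code{score_model};
#'   \code{write_score_model}: invisibly, \code{path}.
#' @export
write_score_model <- function(model, path) {
  yaml::write_yaml(list(
    name = model$name,
    schemes = lapply(model$schemes, function(s) {
      list(variable = s$variable, transform = s$transform,
           thresholds = s$thresholds, weight = s$weight, type = s$type)
    })
  ), path)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  spec <- yaml::read_yaml(path)
  score_model(spec$name, lapply(spec$schemes, function(s) {
    point_scheme(s$variable, thresholds = unlist(s$thresholds),
                 weight = s$weight, transform = s$transform, type = s$type)
  }))
}

#' Flag elevated hs-cTnT
#'
#' Convenience annotation only (not a score cut-off): hs-cTnT at or above
#' 15 ng/L is conventionally reported as elevated.
#'
#' @param hs_ctnt hs-cTnT values, ng/L.
#' @return logical vector.
#' @export
ctnt_elevated <- function(hs_ctnt) hs_ctnt >= 15
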