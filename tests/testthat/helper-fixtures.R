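# Small in-code fixtures shared across test files.

# A hand-written three-patient cohort exercising all field types,
# including both AF levels and a zero-dose patient.
tiny_cohort <- function() {
  as_cohort(data.frame(
    id = c("a1", "a2", "a3"),
    age = c(61, 74, 58),
    sex = c("female", "male", "male"),
    sbp = c(120, 95, 140),
    dbp = c(60, 50, 80),
    hr = c(100, 120, 72),
    hs_ctnt = c(12, 160, 45),
    nt_probnp = c(800, 21000, 4300),
    af_status = c("none", "pre_existing", "new_onset"),
    norepinephrine_dose = c(0, 0.3, 0.05),
    dopamine_dose = c(0, 0, 0),
    other_vasoactive = c(0L, 0L, 1L),
    sofa_neuro = c(0L, 3L, 1L),
    sofa_resp = c(1L, 4L, 2L),
    sofa_renal = c(0L, 2L, 0L),
    sofa_hepatic = c(0L, 1L, 0L),
    sofa_coag = c(0L, 2L, 1L),
    died_30d = c(0L, 1L, 0L),
    stringsAsFactors = FALSE
  ), label = "tiny")
}

# One fully specified patient record as a one-row data.frame; fields are
# overridable so tests can flip a single variable.
make_record <- function(...) {
  rec <- data.frame(
    id = "r1", age = 70, sex = "male",
    sbp = 120, dbp = 70, hr = 90,
    hs_ctnt = 10, nt_probnp = 200, af_status = "none",
    norepinephrine_dose = 0, dopamine_dose = 0, other_vasoactive = 0L,
    sofa_neuro = 0L, sofa_resp = 0L, sofa_renal = 0L,
    sofa_hepatic = 0L, sofa_coag = 0L, died_30d = 0L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (k in names(over)) rec[[k]] <- over[[k]]
  rec
}

# CE-SOFA model with arbitrary but fixed cut-offs for scoring tests.
test_ce_model <- function(af_weight = 2L) {
  ce_sofa_model(ctnt_thresholds = c(15, 40, 90, 200),
                bnp_thresholds = c(300, 1500, 5000, 15000),
                af_weight = af_weight)
}

# Brute-force AUC by explicit all-pairs counting (independent oracle).
auc_brute <- function(scores, labels) {
  ev <- scores[labels == 1]; ne <- scores[labels == 0]
  num <- 0
  for (e in ev) num <- num + sum(e > ne) + 0.5 * sum(e == ne)
  num / (length(ev) * length(ne))
}
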