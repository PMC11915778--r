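test_that("cardiovascular sub-score reproduces the tier table", {
  expect_equal(cardiovascular_sofa(75, 0, 0, FALSE), 0L)
  expect_equal(cardiovascular_sofa(65, 0, 0, FALSE), 1L)
  expect_equal(cardiovascular_sofa(80, 3, 0, FALSE), 2L)   # low-dose dopamine
  expect_equal(cardiovascular_sofa(80, 0, 0, TRUE), 2L)    # dobutamine any dose
  expect_equal(cardiovascular_sofa(80, 8, 0, FALSE), 3L)
  expect_equal(cardiovascular_sofa(80, 0, 0.08, FALSE), 3L)
  expect_equal(cardiovascular_sofa(60, 0, 0.25, FALSE), 4L) # 0.25 > 0.1
  expect_equal(cardiovascular_sofa(80, 20, 0, FALSE), 4L)
  # highest applicable tier wins even with several agents
  expect_equal(cardiovascular_sofa(60, 3, 0.5, TRUE), 4L)
  expect_error(cardiovascular_sofa(80, -1, 0, FALSE), "non-negative")
})

test_that("ordinal point assignment bins left-closed and weights linearly", {
  sch <- point_scheme("x", c(10, 20, 30, 40))
  expect_equal(assign_points(5, sch), 0L)
  expect_equal(assign_points(10, sch), 1L)  # boundary enters the upper bin
  expect_equal(assign_points(39.999, sch), 3L)
  expect_equal(assign_points(40, sch), 4L)
  expect_equal(assign_points(1e6, sch), 4L)
  expect_error(assign_points(NaN, sch), "finite")

  sch3 <- point_scheme("x", c(10, 20, 30, 40), weight = 3)
  expect_equal(assign_points(100, sch3), 12L)
  set.seed(3)
  v <- runif(50, 0, 60)
  for (w in 1:3) {
    schw <- point_scheme("x", c(10, 20, 30, 40), weight = w)
    expect_equal(assign_points(v, schw), w * assign_points(v, sch))
  }

  af2 <- point_scheme("af_status", weight = 2, type = "binary")
  expect_equal(assign_points("pre_existing", af2), 4L)
  expect_equal(assign_points("new_onset", af2), 4L)
  expect_equal(assign_points("none", af2), 0L)
})

test_that("log-transformed schemes bin identically to raw-value binning", {
  sch_log <- point_scheme("hs_ctnt", c(15, 40, 90, 200), transform = "log")
  sch_id <- point_scheme("hs_ctnt", c(15, 40, 90, 200))
  v <- c(3, 15, 39.9, 40, 150, 200, 5000)
  expect_equal(assign_points(v, sch_log), assign_points(v, sch_id))
})

test_that("total SOFA is the component sum over 0-24", {
  expect_equal(total_sofa(rep(0L, 6)), 0L)
  expect_equal(total_sofa(rep(4L, 6)), 24L)
  expect_equal(total_sofa(c(1, 2, 3, 0, 4, 2)), 12L)
  expect_error(total_sofa(c(1, 2, 3, 0, 4, 5)), "\\[0,4\\]")
  expect_error(total_sofa(c(1, 2, 3, 0, 4)), "six")
})

test_that("composite CE-SOFA spans 0-36 and matches hand arithmetic", {
  model <- test_ce_model()
  expect_equal(model$max_score, 36L)

  zero <- as_cohort(make_record())  # map 86.7, no agents, all sub-scores 0
  expect_equal(composite_score(zero, model), 0L)

  maximal <- as_cohort(make_record(
    sofa_neuro = 4L, sofa_resp = 4L, sofa_renal = 4L, sofa_hepatic = 4L,
    sofa_coag = 4L, norepinephrine_dose = 0.5,
    hs_ctnt = 500, nt_probnp = 30000, af_status = "new_onset"))
  expect_equal(composite_score(maximal, model), 36L)

  # SOFA 8 (incl. cardiovascular 3 from norepinephrine 0.05), cTnT bin 2,
  # BNP bin 1, no AF -> 8 + 2 + 1 + 0 = 11
  mid <- as_cohort(make_record(
    sofa_neuro = 2L, sofa_resp = 2L, sofa_coag = 1L,
    norepinephrine_dose = 0.05, hs_ctnt = 50, nt_probnp = 400))
  det <- composite_score(mid, model, detail = TRUE)
  expect_equal(det$sofa, 8L)
  expect_equal(det$hs_ctnt_points, 2L)
  expect_equal(det$nt_probnp_points, 1L)
  expect_equal(det$composite, 11L)

  expect_error(
    composite_score(zero, score_model("bad", list(point_scheme("lactate", 1:4)))),
    "absent")
})

test_that("composite score is monotone in each risk field", {
  model <- test_ce_model()
  set.seed(21)
  bumps <- list(
    hs_ctnt = function(r) { r$hs_ctnt <- r$hs_ctnt * 4; r },
    nt_probnp = function(r) { r$nt_probnp <- r$nt_probnp * 4; r },
    af_status = function(r) { r$af_status <- "new_onset"; r },
    sofa_neuro = function(r) { r$sofa_neuro <- pmin(r$sofa_neuro + 1L, 4L); r },
    sofa_coag = function(r) { r$sofa_coag <- pmin(r$sofa_coag + 1L, 4L); r }
  )
  for (i in 1:40) {
    rec <- make_record(
      hs_ctnt = exp(runif(1, log(3), log(800))),
      nt_probnp = exp(runif(1, log(5), log(40000))),
      sofa_neuro = sample(0:4, 1), sofa_coag = sample(0:4, 1),
      norepinephrine_dose = round(runif(1, 0, 0.4), 2))
    s0 <- composite_score(as_cohort(rec), model)
    for (bump in bumps) {
      expect_gte(composite_score(as_cohort(bump(rec)), model), s0)
    }
  }
})

test_that("score model files round-trip through YAML", {
  model <- test_ce_model()
  path <- tempfile(fileext = ".yaml")
  write_score_model(model, path)
  back <- read_score_model(path)
  expect_equal(back$name, model$name)
  expect_equal(back$max_score, model$max_score)
  expect_equal(lapply(back$schemes, unclass), lapply(model$schemes, unclass))
})

test_that("point scheme construction enforces its invariants", {
  expect_error(point_scheme("x", c(10, 10, 20, 30)), "strictly increasing")
  expect_error(point_scheme("x", c(1, 2, 3, 4), weight = 0), "positive")
  expect_error(point_scheme("x", NULL), "thresholds")
  expect_equal(max_base_points(point_scheme("af", type = "binary")), 2L)
  expect_equal(max_base_points(point_scheme("x", 1:4)), 4L)
})
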