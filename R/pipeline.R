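#' End-to-end derivation/validation demo
#'
#' The complete pipeline at study scale: simulate a synthetic cohort
#' (default n = 503), split it 250/253 into training and test cohorts, run
#' the derivation on the training cohort, and evaluate the selected extended
#' model against the base SOFA score on the test cohort. All artifacts are
#' deterministic given the seed.
#'
#' @param seed integer seed driving simulation and split.
#' @param n cohort size (default 503).
#' @param n_train training size (default 250).
#' @param config optional \code{generator_config}; its \code{n} and
#'   \code{seed} are overridden by the arguments.
#' @param outdir optional directory; when given, writes the cohort CSVs, the
#'   selected model (YAML), the JSON report and a provenance sidecar.
#' @return object of class \code{demo_result}: \code{cohort}, \code{train},
#'   \code{test}, \code{derivation}, \code{evaluation}, \code{report}
#'   (plain list mirrored to JSON).
#' @export
run_demo <- function(seed, n = 503L, n_train = 250L, config = NULL,
                     outdir = NULL) {
  if (is.null(config)) config <- generator_config()
  config$n <- as.integer(n)
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  parts <- split_cohort(cohort, n_train, seed = seed)
  derivation <- derive_extension(parts$train)
  evaluation <- evaluate_extension(parts$test, derivation$model)
  train_eval <- evaluate_extension(parts$train, derivation$model)
  report <- list(
    seed = as.integer(seed),
    n = nrow(cohort),
    n_train = nrow(parts$train),
    n_test = nrow(parts$test),
    train_mortality = mean(parts$train$died_30d),
    test_mortality = mean(parts$test$died_30d),
    selected_model = derivation$model$name,
    schemes = lapply(derivation$model$schemes, function(s) {
      list(variable = s$variable, type = s$type, transform = s$transform,
           thresholds = s$thresholds, weight = s$weight)
    }),
    training_ranking = utils::head(derivation$selection$ranking, 8),
    training = eval_report_list(train_eval),
    test = eval_report_list(evaluation)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
    write_cohort(parts$train, file.path(outdir, "train.csv"))
    write_cohort(parts$test, file.path(outdir, "test.csv"))
    write_score_model(derivation$model, file.path(outdir, "model.yaml"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_provenance(file.path(outdir, "provenance.json"), "demo",
                     seed = seed, config = config)
  }
  structure(list(cohort = cohort, train = parts$train, test = parts$test,
                 derivation = derivation, evaluation = evaluation,
                 report = report),
            class = "demo_result")
}

#' @export
print.demo_result <- function(x, ...) {
  cat(sprintf("Demo pipeline, seed %d: %d patients (%d train / %d test)\n",
              x$report$seed, x$report$n, x$report$n_train, x$report$n_test))
  cat(sprintf("Selected model: %s\n", x$report$selected_model))
  print(x$evaluation)
  invisible(x)
}

# Provenance sidecar: config + seed + package version, written next to every
# artifact a run produces. No timestamps, so reruns are byte-identical.
write_provenance <- function(path, subcommand, seed = NULL, config = NULL) {
  prov <- list(
    tool = "cesofa",
    version = as.character(utils::packageVersion("cesofa")),
    subcommand = subcommand,
    seed = if (!is.null(seed)) as.integer(seed),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(prov[!vapply(prov, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

# --- command-line front end -------------------------------------------------

.cli_usage <- paste(
  "usage: cesofa <subcommand> [flags]",
  "",
  "subcommands:",
  "  simulate --seed S [--n N] [--config cfg.yaml] --out cohort.csv",
  "  split    --in cohort.csv --n-train K --seed S --out-train a.csv --out-test b.csv",
  "  derive   --in train.csv --out-model model.yaml [--out report.json]",
  "  score    --in cohort.csv --model model.yaml --out scored.csv",
  "  evaluate --in cohort.csv --model model.yaml --out report.json [--no-base]",
  "  demo     --seed S [--n N] [--n-train K] --out outdir",
  sep = "\n")

.parse_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (key == "no-base") {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i == length(argv)) stop("flag --", key, " needs a value", call. = FALSE)
      flags[[key]] <- argv[i + 1]
      i <- i + 2
    }
  }
  flags
}

.need <- function(flags, key) {
  if (is.null(flags[[key]])) stop("missing required flag --", key, call. = FALSE)
  flags[[key]]
}

# Apply key: value overrides from a YAML config file onto the default
# generator_config.
.config_from_file <- function(path) {
  over <- yaml::read_yaml(path)
  args <- unclass(generator_config())
  for (k in names(over)) {
    if (!k %in% names(args)) stop("unknown config key: ", k, call. = FALSE)
    args[[k]] <- if (k == "effect_log_odds") unlist(over[[k]]) else over[[k]]
  }
  do.call(generator_config, args[!vapply(args, is.null, logical(1))])
}

#' Command-line entry point
#'
#' Dispatches the \code{simulate}, \code{split}, \code{derive},
#' \code{score}, \code{evaluate} and \code{demo} subcommands over the
#' package's functions. Installed alongside the package as the
#' \code{cli/cesofa} Rscript; callable directly from R for testing. Every
#' run writes a provenance sidecar (config + seed + version) next to its
#' outputs; machine-readable output is JSON/CSV only, diagnostics go to
#' stderr.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return exit status, invisibly: 0 on success, 1 on error.
#' @export
cesofa_cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
      message(.cli_usage)
      return(invisible(0L))
    }
    sub <- argv[1]
    flags <- .parse_flags(argv[-1])
    switch(sub,
      simulate = {
        cfg <- if (!is.null(flags$config)) .config_from_file(flags$config)
               else generator_config()
        cfg$seed <- as.integer(.need(flags, "seed"))
        if (!is.null(flags$n)) cfg$n <- as.integer(flags$n)
        out <- .need(flags, "out")
        write_cohort(generate_cohort(cfg), out)
        write_provenance(paste0(out, ".provenance.json"), "simulate",
                         seed = cfg$seed, config = cfg)
      },
      split = {
        cohort <- read_cohort(.need(flags, "in"))
        seed <- as.integer(.need(flags, "seed"))
        parts <- split_cohort(cohort, as.integer(.need(flags, "n-train")),
                              seed = seed)
        write_cohort(parts$train, .need(flags, "out-train"))
        write_cohort(parts$test, .need(flags, "out-test"))
        write_provenance(paste0(.need(flags, "out-train"), ".provenance.json"),
                         "split", seed = seed)
      },
      derive = {
        train <- read_cohort(.need(flags, "in"))
        rep <- derive_extension(train)
        write_score_model(rep$model, .need(flags, "out-model"))
        if (!is.null(flags$out)) {
          jsonlite::write_json(list(
            screen = rep$screen$summary,
            retained = as.list(rep$retained),
            ranking = rep$selection$ranking,
            selected = rep$model$name
          ), flags$out, auto_unbox = TRUE, digits = 10, pretty = TRUE)
        }
        write_provenance(paste0(.need(flags, "out-model"), ".provenance.json"),
                         "derive")
      },
      score = {
        cohort <- read_cohort(.need(flags, "in"))
        model <- read_score_model(.need(flags, "model"))
        detail <- composite_score(cohort, model, detail = TRUE)
        utils::write.csv(cbind(as.data.frame(cohort), detail),
                         .need(flags, "out"), row.names = FALSE, quote = FALSE)
      },
      evaluate = {
        cohort <- read_cohort(.need(flags, "in"))
        model <- read_score_model(.need(flags, "model"))
        rep <- evaluate_extension(cohort, model,
                                  compare_base = is.null(flags[["no-base"]]))
        jsonlite::write_json(eval_report_list(rep), .need(flags, "out"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE)
      },
      demo = {
        run_demo(seed = as.integer(.need(flags, "seed")),
                 n = as.integer(flags$n %||% 503L),
                 n_train = as.integer(flags[["n-train"]] %||% 250L),
                 outdir = .need(flags, "out"))
      },
      stop("unknown subcommand: ", sub, "\n", .cli_usage, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("cesofa error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
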