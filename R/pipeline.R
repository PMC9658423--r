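#' Pipeline configuration
#'
#' Validated configuration for the end-to-end run: spectra source, synthetic
#' study settings, preprocessing settings, chemometrics settings, and the
#' report directory. Unknown keys anywhere are rejected rather than
#' silently ignored.
#'
#' @param input `"simulate"` (generate the study) or a named list
#'   `list(sers = <csv>, indexes = <csv>)` pointing at a wide SERS spectra
#'   CSV and a per-sample indexes CSV (`sample_id`, `index1_mean` ..
#'   `index6_mean`).
#' @param sim named list of overrides for [sim_config()].
#' @param preprocess named list of overrides for [preprocess_config()].
#' @param chemometrics named list: `max_factors` (default 10),
#'   `split_fraction` (0.75), `split_mode` (`"replicate_random"`),
#'   `indexes` (which of 1..6 to model, default all six).
#' @param report_dir output directory (created).
#' @param seed master integer seed; every stochastic stage derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate",
                            sim = list(),
                            preprocess = list(),
                            chemometrics = list(),
                            report_dir = tempfile("anthostab_run_"),
                            seed = 1L) {
  .check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", where,
                   paste(bad, collapse = ", ")))
  }
  .check_keys(sim, setdiff(names(formals(sim_config)), ""), "sim")
  .check_keys(preprocess, names(formals(preprocess_config)), "preprocess")
  chemo_defaults <- list(max_factors = 10, split_fraction = 0.75,
                         split_mode = "replicate_random",
                         indexes = 1:6)
  .check_keys(chemometrics, names(chemo_defaults), "chemometrics")
  chemometrics <- utils::modifyList(chemo_defaults, chemometrics)
  if (!is.character(input)) {
    .check_keys(input, c("sers", "indexes"), "input")
    if (is.null(input$sers) || is.null(input$indexes))
      stop("file input needs both 'sers' and 'indexes' paths")
  } else if (!identical(input, "simulate")) {
    stop("input must be \"simulate\" or a list(sers=, indexes=)")
  }
  if (!"seed" %in% names(sim)) sim$seed <- as.integer(seed)
  structure(list(input = input, sim = sim, preprocess = preprocess,
                 chemometrics = chemometrics,
                 report_dir = report_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any of the [pipeline_config()] sections.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  # yaml gives region lists as nested lists of length-2 vectors
  if (!is.null(raw$preprocess$regions))
    raw$preprocess$regions <- lapply(raw$preprocess$regions, unlist)
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.load_inputs <- function(config) {
  if (identical(config$input, "simulate")) {
    simcfg <- do.call(sim_config, config$sim)
    study <- simulate_study(simcfg)
    idx <- lapply(names(study$uvvis), function(id)
      compute_indexes(study$uvvis[[id]], sample_id = id))
    list(sers = study$sers, index_objects = idx,
         indexes = indexes_table(idx), truth = study$truth)
  } else {
    sers <- read_spectra_csv(config$input$sers, kind = "raman")
    indexes <- utils::read.csv(config$input$indexes,
                               stringsAsFactors = FALSE)
    need <- c("sample_id", paste0("index", 1:6, "_mean"))
    if (!all(need %in% names(indexes)))
      stop("indexes CSV must carry columns: ", paste(need, collapse = ", "))
    list(sers = sers, index_objects = NULL, indexes = indexes,
         truth = NULL)
  }
}

#' Run the full pipeline
#'
#' Stages: load or simulate spectra; compute the six stability indexes;
#' preprocess the SERS matrix; for every requested index, split
#' train/validation, choose the factor count by LOOCV/PRESS on the
#' training set, fit the PLS1 model, and evaluate RMSEP and R^2 on the
#' validation set; write the loading-band diagnostics; and record a
#' manifest (configuration, seeds, versions, output hashes). A rerun with
#' the same configuration and seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return the report directory path, invisibly. Outputs written there:
#'   `indexes.csv`, `models/indexN.json`, `validation.json`,
#'   `validation.csv`, `loadings.csv`, `diagnostics.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$report_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$report_dir, "models"), showWarnings = FALSE)

  inputs <- .stage("load", .load_inputs(config))
  sers <- inputs$sers
  idx_tab <- inputs$indexes

  .stage("indexes", {
    out <- idx_tab
    out[] <- lapply(out, function(col)
      if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col)
    utils::write.csv(out, file.path(config$report_dir, "indexes.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  if (length(unique(sers$labels)) < 2)
    stop("stage 'train' refused: insufficient classes (need >= 2 samples)")

  ppcfg <- do.call(preprocess_config, config$preprocess)
  pp <- .stage("preprocess", preprocess_chain(sers, ppcfg))

  cm <- config$chemometrics
  validation <- list()
  loadings <- list(axis = pp$axis)
  for (k in cm$indexes) {
    col <- paste0("index", k, "_mean")
    ymap <- stats::setNames(idx_tab[[col]], idx_tab$sample_id)
    if (anyNA(ymap[pp$labels]))
      stop("stage 'train' failed: no index for sample(s) ",
           paste(unique(pp$labels[is.na(ymap[pp$labels])]), collapse = ", "))
    mat <- pp
    mat$y <- unname(ymap[pp$labels])
    res <- .stage(paste0("train index", k), {
      sp <- split_train_validation(mat, fraction = cm$split_fraction,
                                   mode = cm$split_mode,
                                   seed = config$seed + k)
      cv <- loocv(sp$train, max_factors = cm$max_factors)
      model <- pls1(sp$train, n_factors = cv$chosen_factors)
      ev <- evaluate(model, sp$validation)
      list(split = sp, cv = cv, model = model, ev = ev)
    })
    write_pls1_json(res$model,
                    file.path(config$report_dir, "models",
                              sprintf("index%d.json", k)))
    loadings[[sprintf("index%d_coef", k)]] <- res$model$coefficients
    validation[[sprintf("index%d", k)]] <- list(
      index = k,
      chosen_factors = res$cv$chosen_factors,
      press_by_factor = res$cv$press_by_factor,
      rmsecv = res$cv$rmsecv_at_chosen,
      r2_cv = res$cv$r2_cv,
      rmsep = res$ev$rmsep,
      r2_val = res$ev$r2,
      r2_val_determination = res$ev$r2_determination,
      n_train = res$cv$n, n_validation = res$ev$n,
      split_mode = cm$split_mode, split_seed = config$seed + k)
    if (k == min(cm$indexes)) {
      diag <- loading_diagnostics(res$model)
      utils::write.csv(diag, file.path(config$report_dir,
                                       "diagnostics.csv"),
                       row.names = FALSE)
    }
  }

  jsonlite::write_json(validation,
                       file.path(config$report_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  vtab <- do.call(rbind, lapply(validation, function(v)
    data.frame(v[c("index", "chosen_factors", "rmsecv", "r2_cv",
                   "rmsep", "r2_val")])))
  utils::write.csv(vtab, file.path(config$report_dir, "validation.csv"),
                   row.names = FALSE)
  ldf <- as.data.frame(lapply(loadings, function(col)
    formatC(col, digits = 15, format = "g")))
  utils::write.csv(ldf, file.path(config$report_dir, "loadings.csv"),
                   row.names = FALSE, quote = FALSE)

  outputs <- c("indexes.csv", "validation.json", "validation.csv",
               "loadings.csv", "diagnostics.csv",
               file.path("models", sprintf("index%d.json", cm$indexes)))
  hashes <- vapply(outputs, function(f)
    unname(tools::md5sum(file.path(config$report_dir, f))), character(1))
  manifest <- list(config = unclass(config),
                   preprocess_hash = attr(pp, "provenance_hash"),
                   seed = config$seed,
                   versions = list(package = "anthostab 0.1.0",
                                   r = paste(R.version$major,
                                             R.version$minor, sep = ".")),
                   output_hashes = as.list(hashes))
  manifest$manifest_hash <- config_hash(manifest)
  jsonlite::write_json(manifest,
                       file.path(config$report_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$report_dir)
}

.cli_usage <- function() {
  cat("usage: anthostab <simulate|indexes|train|predict|report> [options]\n",
      "  options: --config <yaml>  --seed <int>  --out <dir|file>\n",
      "           --model <json>   --spectra <csv>  --verbose\n", sep = "")
}

.cli_flags <- function(args) {
  flags <- list(verbose = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") { flags$verbose <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("flag ", a, " needs a value")
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic study spectra and truth),
#' `indexes` (stability indexes CSV), `train` (full pipeline run),
#' `predict` (apply a serialized model to a spectra CSV), `report`
#' (summarize a run directory). Returns the process exit code instead of
#' calling `quit()`, so it is scriptable and testable; the installed
#' wrapper script `inst/scripts/anthostab` forwards `commandArgs()` and
#' exits with the returned code.
#'
#' @param args character vector of CLI arguments (default: the actual
#'   command line).
#' @return integer exit code: 0 success, 1 failure, 2 usage error.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { .cli_usage(); return(2L) }
  sub <- args[1]
  if (!sub %in% c("simulate", "indexes", "train", "predict", "report")) {
    .cli_usage(); return(2L)
  }
  code <- tryCatch({
    flags <- .cli_flags(args[-1])
    log <- function(...) if (flags$verbose)
      message("[anthostab ", sub, "] ", ...)
    config <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
      else pipeline_config()
    if (!is.null(flags$seed)) {
      config$seed <- as.integer(flags$seed)
      if (identical(config$input, "simulate"))
        config$sim$seed <- config$seed
    }
    if (!is.null(flags$out) && sub == "train")
      config$report_dir <- flags$out

    if (sub == "simulate") {
      out <- if (!is.null(flags$out)) flags$out else config$report_dir
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      log("generating study with seed ", config$seed)
      study <- simulate_study(do.call(sim_config, config$sim))
      write_spectra_csv(study$sers, file.path(out, "sers.csv"))
      utils::write.csv(study$truth, file.path(out, "truth.csv"),
                       row.names = FALSE)
      message("wrote ", file.path(out, "sers.csv"), " and truth.csv")
    } else if (sub == "indexes") {
      inputs <- .load_inputs(config)
      out <- if (!is.null(flags$out)) flags$out else "indexes.csv"
      utils::write.csv(inputs$indexes, out, row.names = FALSE)
      message("wrote ", out)
    } else if (sub == "train") {
      log("pipeline run into ", config$report_dir)
      dir <- run_pipeline(config)
      message("run complete: ", dir)
    } else if (sub == "predict") {
      if (is.null(flags$model) || is.null(flags$spectra))
        stop("predict needs --model and --spectra")
      model <- read_pls1_json(flags$model)
      raw <- read_spectra_csv(flags$spectra, kind = "raman")
      mat <- if (ncol(raw$X) == model$p) raw else
        preprocess_chain(raw, do.call(preprocess_config,
                                      config$preprocess))
      if (ncol(mat$X) != model$p)
        stop("spectra have ", ncol(mat$X),
             " features after preprocessing; model expects ", model$p)
      pred <- predict(model, mat)
      out <- if (!is.null(flags$out)) flags$out else "predictions.csv"
      utils::write.csv(data.frame(sample_id = mat$labels,
                                  prediction = pred),
                       out, row.names = FALSE)
      message("wrote ", out)
    } else if (sub == "report") {
      dir <- if (!is.null(flags$out)) flags$out else config$report_dir
      vfile <- file.path(dir, "validation.json")
      if (!file.exists(vfile)) stop("no validation.json under ", dir)
      v <- jsonlite::read_json(vfile, simplifyVector = TRUE)
      for (nm in names(v))
        cat(sprintf(
          "%s: factors %d, RMSECV %.4g, R2cv %.3f, RMSEP %.4g, R2val %.3f\n",
          nm, v[[nm]]$chosen_factors, v[[nm]]$rmsecv, v[[nm]]$r2_cv,
          v[[nm]]$rmsep, v[[nm]]$r2_val))
    }
    0L
  }, error = function(e) {
    message("anthostab ", sub, ": ", conditionMessage(e))
    1L
  })
  code
}
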