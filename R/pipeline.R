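# End-to-end orchestration: one config describes a study run; the pipeline
# builds or loads structures, aligns, computes fields, trains PLS with LOO
# component selection, runs the validation battery, exports contours, and
# writes a machine-readable report bundle.
#
# Two modes:
#   metrics_only - feed an activity table that already carries model
#       predictions (e.g. the packaged printed table) through the external-
#       validation metric layer; tight and fully deterministic.
#   full - structures -> alignment -> fields -> PLS -> validation; the
#       training statistics depend on conformers and charges, so they are
#       approximate relative to any particular published run.

#' Build a run configuration
#'
#' Defaults equal the printed study settings wherever the study prints one:
#' grid spacing 2.0 A, 30 kcal/mol truncation, attenuation 0.3, bootstrap
#' 100 runs, 10x10-fold cross-validation, 50 y-randomizations.
#'
#' @param mode `"metrics_only"` or `"full"`.
#' @param activity path to an activity CSV
#'   (`compound_id,pIC50,set_label[,pred_comfa,pred_comsia]`), or `NULL` for
#'   the packaged table.
#' @param structures `"packaged"` (build the thiourea series), or a path to
#'   an SDF/SMILES file (full mode).
#' @param models character vector of predictions/field models to evaluate.
#' @param template alignment template compound id.
#' @param scaffold alignment SMARTS.
#' @param spacing,padding,cutoff,alpha,min_sigma,scaling field settings (see
#'   [assemble_block()]); `min_sigma = NULL` uses the per-model default.
#' @param max_comp PLS component-scan bound.
#' @param bootstrap_runs,kfold_folds,kfold_repeats,yrand_runs validation
#'   battery sizes; set to 0 to skip a stage.
#' @param fav_pct,disfav_pct contour percentile thresholds.
#' @param seed master seed for every stochastic stage.
#' @param outdir output directory (`NULL`: nothing written).
#' @param ids optional compound-id subset (e.g. for fast smoke runs).
#' @return `qsar_run_config` list.
#' @export
run_config <- function(mode = c("metrics_only", "full"), activity = NULL,
                       structures = "packaged", ids = NULL,
                       models = c("comfa", "comsia"), template = "70",
                       scaffold = thiourea_scaffold_smarts(), spacing = 2.0,
                       padding = 4.0, cutoff = 30, alpha = 0.3,
                       min_sigma = NULL, scaling = "comfa_std",
                       max_comp = NULL, bootstrap_runs = 100L,
                       kfold_folds = 10L, kfold_repeats = 10L,
                       yrand_runs = 50L, fav_pct = 80, disfav_pct = 20,
                       seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "qsar_run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return `qsar_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

load_activity_table <- function(config) {
  if (is.null(config$activity)) return(thiourea_activity())
  act <- read.csv(config$activity, colClasses = c(compound_id = "character"))
  stopifnot(all(c("compound_id", "pIC50") %in% names(act)))
  act
}

#' Run the configured pipeline
#'
#' @param config a [run_config()].
#' @return report bundle: list with one entry per model carrying the
#'   training statistics (full mode), the external [validate_external()]
#'   report, robustness results, per-compound predictions, and contour sets;
#'   plus the resolved `config`. Written as JSON/CSV/DX files under
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qsar_run_config"))
  act <- load_activity_table(config)
  if (!is.null(config$ids))
    act <- act[act$compound_id %in% as.character(config$ids), ]
  split <- split_dataset(act, mode = "printed")
  report <- list(config = unclass(config), models = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (config$mode == "metrics_only") {
    for (m in config$models) {
      col <- paste0("pred_", m)
      if (!col %in% names(act))
        stop("pipeline stage [validate] failed: no column ", col,
             " in the activity table", call. = FALSE)
      test <- act$set_label == "test"
      val <- stage("validate", validate_external(
        act$pIC50[test], act[[col]][test], act$pIC50[!test]))
      train_pred <- act[[col]][!test]
      train_obs <- act$pIC50[!test]
      report$models[[m]] <- list(
        external = val,
        training = list(r2 = cor(train_obs, train_pred)^2,
                        rmse = rmsep(train_obs, train_pred)),
        predictions = data.frame(compound_id = act$compound_id,
                                 observed = act$pIC50,
                                 predicted = act[[col]],
                                 set_label = act$set_label))
    }
  } else {
    set <- stage("structures", {
      if (identical(config$structures, "packaged")) {
        built <- build_thiourea_series(ids = act$compound_id,
                                       seed = config$seed)
        built$set
      } else {
        load_molecules(config$structures, seed = config$seed)
      }
    })
    aligned <- stage("alignment",
                     scaffold_align(set, config$template, config$scaffold))
    act <- act[match(names(aligned), act$compound_id), ]
    split <- split_dataset(act, mode = "printed")
    grid <- stage("grid", make_grid(aligned, config$spacing, config$padding))
    for (m in config$models) {
      block <- stage("fields", assemble_block(
        aligned, grid = grid, model = m, cutoff = config$cutoff,
        alpha = config$alpha, min_sigma = config$min_sigma,
        scaling = config$scaling))
      tr <- match(split$train, rownames(block$X))
      te <- match(split$test, rownames(block$X))
      Xtr <- block$X[tr, , drop = FALSE]; ytr <- act$pIC50[tr]
      sel <- stage("pls", select_components(Xtr, ytr, config$max_comp))
      fit <- stage("pls", fit_pls(Xtr, ytr, sel$ncomp))
      st <- final_stats(fit)
      pred_all <- predict(fit, block$X)
      val <- NULL
      if (length(te) >= 2L)
        val <- stage("validate", validate_external(
          act$pIC50[te], pred_all[te], ytr))
      robust <- list()
      if (config$yrand_runs > 0)
        robust$y_randomization <- stage("y_randomization", y_randomization(
          Xtr, ytr, config$yrand_runs, seed = config$seed,
          max_comp = config$max_comp))
      if (config$bootstrap_runs > 0)
        robust$bootstrap <- stage("bootstrap", bootstrap_r2(
          Xtr, ytr, sel$ncomp, config$bootstrap_runs, seed = config$seed))
      if (config$kfold_repeats > 0)
        robust$kfold <- stage("kfold", repeated_kfold_q2(
          Xtr, ytr, sel$ncomp, config$kfold_folds, config$kfold_repeats,
          seed = config$seed))
      sc <- stage("contours", stdev_coeff_grid(fit, block))
      contours <- lapply(names(sc), function(k)
        extract_contours(sc[[k]], block$grid, config$fav_pct,
                         config$disfav_pct, field = k))
      names(contours) <- names(sc)
      report$models[[m]] <- list(
        training = list(q2 = sel$q2, sep = sel$sep, pcs = sel$ncomp,
                        r2_ncv = st$r2_ncv, see = st$see, f = st$f,
                        contributions = field_contributions(fit, block)),
        external = val, robustness = robust,
        predictions = data.frame(compound_id = act$compound_id,
                                 observed = act$pIC50,
                                 predicted = pred_all,
                                 set_label = act$set_label),
        stdev_coeff = sc, contours = contours, block_dim = dim(block$X))
    }
    report$grid <- grid
  }
  if (!is.null(config$outdir)) write_report_bundle(report, config)
  invisible(report)
}

write_report_bundle <- function(report, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(drop_nonserializable(unclass(config)),
                   file.path(config$outdir, "config.yaml"))
  for (m in names(report$models)) {
    rm_ <- report$models[[m]]
    write.csv(rm_$predictions,
              file.path(config$outdir, paste0("predictions_", m, ".csv")),
              row.names = FALSE)
    if (!is.null(rm_$stdev_coeff)) {
      grid <- attr(rm_$stdev_coeff, "grid")
      for (k in names(rm_$stdev_coeff))
        export_dx(rm_$stdev_coeff[[k]], grid,
                  file.path(config$outdir,
                            sprintf("stdev_coeff_%s_%s.dx", m, k)))
    }
  }
  summary <- lapply(report$models, function(x)
    drop_nonserializable(x[setdiff(names(x),
                                   c("predictions", "stdev_coeff", "contours"))]))
  jsonlite::write_json(summary, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(c("qsar3d report bundle", paste("models:",
               paste(names(report$models), collapse = ", ")),
               paste("written:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(config$outdir, "MANIFEST"))
  invisible(NULL)
}

# strip S3 classes and functions so a report nests cleanly into YAML/JSON
drop_nonserializable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- unclass(x)
    out <- lapply(x, drop_nonserializable)
    return(out[!vapply(out, is.null, logical(1)) | vapply(x, is.null, logical(1))])
  }
  x
}
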