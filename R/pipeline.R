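PIPELINE_ENDPOINTS <- c("collagen", "laminin", "nidogen", "treg", "cd8",
                        "ecm_overall", "immune_overall")
REGION_MODES <- c("intratumoral_only", "combined")

#' End-to-end run configuration
#'
#' Bundles the stage configurations and the analysis grid (endpoints x
#' sequences x region modes). A single master seed deterministically derives
#' every stage seed, so one number reproduces the whole run.
#'
#' @param cohort A [cohort_config()].
#' @param region A [region_config()].
#' @param discretization A [discretization_config()].
#' @param selection A [selection_config()].
#' @param evaluation An [eval_config()].
#' @param endpoints Subset of `collagen, laminin, nidogen, treg, cd8,
#'   ecm_overall, immune_overall`.
#' @param sequences Subset of the five sequence tags.
#' @param region_modes Subset of `intratumoral_only`, `combined`.
#' @param margin_sensitivity Optional second annulus margin in mm (e.g. 8)
#'   for a sensitivity re-run of the combined models.
#' @param master_seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       region = region_config(),
                       discretization = discretization_config(),
                       selection = selection_config(),
                       evaluation = eval_config(),
                       endpoints = c("collagen", "treg"),
                       sequences = names(cohort$sequences),
                       region_modes = REGION_MODES,
                       margin_sensitivity = NULL,
                       master_seed = 1L) {
  if (length(endpoints) == 0L || !all(endpoints %in% PIPELINE_ENDPOINTS))
    stopf("endpoints must be a nonempty subset of: %s",
          paste(PIPELINE_ENDPOINTS, collapse = ", "))
  if (length(sequences) == 0L || !all(sequences %in% names(cohort$sequences)))
    stopf("sequences must be a nonempty subset of the cohort's sequences")
  if (length(region_modes) == 0L || !all(region_modes %in% REGION_MODES))
    stopf("region_modes must be a nonempty subset of: %s",
          paste(REGION_MODES, collapse = ", "))
  if (!is.null(margin_sensitivity) &&
      (!is_scalar_num(margin_sensitivity) || margin_sensitivity <= 0))
    stopf("margin_sensitivity must be a positive margin in mm")
  structure(list(cohort = cohort, region = region,
                 discretization = discretization, selection = selection,
                 evaluation = evaluation, endpoints = endpoints,
                 sequences = sequences, region_modes = region_modes,
                 margin_sensitivity = margin_sensitivity,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Accepts a `run_config`, a plain nested list, or a path to a JSON document;
#' fills defaults, checks every invariant, and rejects unknown keys (typo
#' guard). On failure, all collected problems are reported together.
#'
#' @param x A `run_config`, list, or JSON file path.
#' @return A validated `run_config`.
#' @export
validate_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (!is.list(x)) stopf("config must be a run_config, list, or JSON path")
  errors <- character(0)
  builders <- list(cohort = cohort_config, region = region_config,
                   discretization = discretization_config,
                   selection = selection_config, evaluation = eval_config)
  top_keys <- c(names(builders), "endpoints", "sequences", "region_modes",
                "margin_sensitivity", "master_seed")
  unknown <- setdiff(names(x), top_keys)
  if (length(unknown))
    errors <- c(errors, sprintf("unknown key(s): %s",
                                paste(unknown, collapse = ", ")))
  args <- list()
  for (nm in names(builders)) {
    sub <- if (is.null(x[[nm]])) list() else as.list(x[[nm]])
    bad <- setdiff(names(sub), names(formals(builders[[nm]])))
    if (length(bad)) {
      errors <- c(errors, sprintf("%s: unknown key(s): %s", nm,
                                  paste(bad, collapse = ", ")))
      next
    }
    res <- tryCatch(do.call(builders[[nm]], sub), error = function(e)
      conditionMessage(e))
    if (is.character(res)) errors <- c(errors, sprintf("%s: %s", nm, res))
    else args[[nm]] <- res
  }
  if (length(errors)) stopf("invalid configuration:\n- %s",
                            paste(errors, collapse = "\n- "))
  extra <- x[intersect(names(x), c("endpoints", "sequences", "region_modes",
                                   "margin_sensitivity", "master_seed"))]
  do.call(run_config, c(args, extra))
}

#' Run the full pipeline
#'
#' Executes simulate -> resample -> regions -> extract -> normalize/split ->
#' stability-select/fit -> evaluate for every requested endpoint x sequence x
#' region-mode cell, fully deterministically under the master seed. A failing
#' cell records its error and the run continues for sibling cells.
#'
#' The `combined` model's candidate pool is the union of the
#' intratumoral-ROI features and the combined-ROI (tumor + annulus) features
#' (prefixed `IT_` / `CB_`), twice 1618 candidates.
#'
#' @param config A `run_config` (or anything [validate_config()] accepts).
#' @param cohort Optional pre-generated `tme_cohort` (default: generated from
#'   `config$cohort` with a derived seed).
#' @param verbose Print stage progress?
#' @return A `tme_run_report`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, verbose = FALSE) {
  config <- validate_config(config)
  ms <- config$master_seed
  if (is.null(cohort)) {
    ccfg <- config$cohort
    ccfg$seed <- derive_seed(ms, "cohort")
    cohort <- generate_cohort(ccfg)
  }
  n <- cohort$config$n_cases
  if (verbose) message("extracting features for ", n, " cases")
  tables <- extract_cohort(cohort, config$sequences, config$region,
                           config$discretization, verbose = verbose)
  tables8 <- NULL
  if (!is.null(config$margin_sensitivity)) {
    rc <- config$region
    rc$margin_mm <- config$margin_sensitivity
    tables8 <- extract_cohort(cohort, config$sequences, rc,
                              config$discretization, verbose = verbose)
  }
  split <- split_cohort(n, config$selection$split_ratio,
                        seed = derive_seed(ms, "split"))
  cells <- list()
  run_cell <- function(tabs, endpoint, sq, mode, tag) {
    y <- panel_labels(cohort$panel, endpoint)
    X <- if (mode == "intratumoral_only") {
      m <- tabs[[sq]]$intratumoral
      colnames(m) <- paste0("IT_", colnames(m)); m
    } else {
      it <- tabs[[sq]]$intratumoral; cb <- tabs[[sq]]$combined
      colnames(it) <- paste0("IT_", colnames(it))
      colnames(cb) <- paste0("CB_", colnames(cb))
      cbind(it, cb)
    }
    Xn <- suppressWarnings(
      zscore_normalize(X, config$selection$normalization_scope,
                       train_idx = split$train))
    scfg <- config$selection
    scfg$seed <- derive_seed(ms, paste("sel", tag))
    sel <- stability_select(Xn[split$train, , drop = FALSE], y[split$train], scfg)
    sig <- top_k_signature(sel, scfg)
    if (length(sig) == 0L) stopf("no feature ever selected")
    model <- fit_signature_model(Xn[split$train, , drop = FALSE],
                                 y[split$train], sig,
                                 endpoint = endpoint, region_mode = mode,
                                 selection = sel)
    test_scores <- predict(model, Xn[split$test, , drop = FALSE])
    ecfg <- config$evaluation
    ecfg$seed <- derive_seed(ms, paste("eval", tag))
    list(endpoint = endpoint, sequence = sq, mode = mode,
         signature = sig, model = model,
         test_scores = test_scores, test_labels = y[split$test],
         auc = roc_auc(test_scores, y[split$test]),
         auc_ci = bootstrap_auc_ci(test_scores, y[split$test], ecfg),
         confusion = suppressWarnings(
           confusion_metrics(test_scores, y[split$test], model$threshold)))
  }
  for (endpoint in config$endpoints)
    for (sq in config$sequences)
      for (mode in config$region_modes) {
        tag <- paste(endpoint, sq, mode, sep = "|")
        if (verbose) message("cell: ", tag)
        cells[[tag]] <- tryCatch(
          run_cell(tables, endpoint, sq, mode, tag),
          error = function(e) list(endpoint = endpoint, sequence = sq,
                                   mode = mode,
                                   error = conditionMessage(e)))
      }
  # paired DeLong: intratumoral-only vs combined per endpoint x sequence
  delong <- list()
  if (all(REGION_MODES %in% config$region_modes))
    for (endpoint in config$endpoints)
      for (sq in config$sequences) {
        a <- cells[[paste(endpoint, sq, "intratumoral_only", sep = "|")]]
        b <- cells[[paste(endpoint, sq, "combined", sep = "|")]]
        if (is.null(a$error) && is.null(b$error))
          delong[[paste(endpoint, sq, sep = "|")]] <-
            tryCatch(delong_test(b$test_scores, a$test_scores, a$test_labels),
                     error = function(e) list(error = conditionMessage(e)))
      }
  # decision curves for the representative endpoints, when available
  dcc <- decision_curve_config()
  dcurves <- list()
  for (endpoint in intersect(c("collagen", "treg"), config$endpoints))
    for (sq in config$sequences) {
      cell <- cells[[paste(endpoint, sq, "combined", sep = "|")]]
      if (!is.null(cell) && is.null(cell$error))
        dcurves[[paste(endpoint, sq, sep = "|")]] <- decision_curve(
          cell$test_scores, cell$test_labels, dcc,
          calibration_range = range(cell$model$scores_train))
    }
  sens <- NULL
  if (!is.null(tables8)) {
    sens <- list()
    for (endpoint in config$endpoints)
      for (sq in config$sequences) {
        tag <- paste(endpoint, sq, "combined", sep = "|")
        sens[[paste(endpoint, sq, sep = "|")]] <- tryCatch({
          cell8 <- run_cell(tables8, endpoint, sq, "combined",
                            paste0(tag, "@", config$margin_sensitivity, "mm"))
          base <- cells[[tag]]
          list(margin_mm = config$margin_sensitivity,
               auc_main = if (is.null(base$error)) base$auc else NA_real_,
               auc_sensitivity = cell8$auc)
        }, error = function(e) list(error = conditionMessage(e)))
      }
  }
  structure(list(config = config, cohort_panel = cohort$panel,
                 split = split, cells = cells, delong = delong,
                 decision_curves = dcurves, margin_sensitivity = sens),
            class = "tme_run_report")
}

#' @export
print.tme_run_report <- function(x, ...) {
  cat("<tme_run_report>\n")
  for (tag in names(x$cells)) {
    cell <- x$cells[[tag]]
    if (!is.null(cell$error))
      cat(sprintf("  %-45s FAILED: %s\n", tag, cell$error))
    else
      cat(sprintf("  %-45s AUC %.3f (%.3f, %.3f)\n", tag, cell$auc,
                  cell$auc_ci[["low"]], cell$auc_ci[["high"]]))
  }
  if (length(x$delong)) {
    cat("DeLong (combined vs intratumoral-only):\n")
    for (tag in names(x$delong)) {
      d <- x$delong[[tag]]
      if (is.null(d$error))
        cat(sprintf("  %-35s delta %.3f, p = %.3f\n", tag, d$delta, d$p))
    }
  }
  invisible(x)
}

#' Summarize a run report as a data.frame
#'
#' @param object A `tme_run_report`.
#' @param ... Unused.
#' @return Data.frame with one row per evaluated cell.
#' @export
summary.tme_run_report <- function(object, ...) {
  rows <- lapply(object$cells, function(cell) {
    if (!is.null(cell$error))
      data.frame(endpoint = cell$endpoint, sequence = cell$sequence,
                 mode = cell$mode, auc = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, error = cell$error)
    else
      data.frame(endpoint = cell$endpoint, sequence = cell$sequence,
                 mode = cell$mode, auc = cell$auc,
                 ci_low = cell$auc_ci[["low"]], ci_high = cell$auc_ci[["high"]],
                 error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
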