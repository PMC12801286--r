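# Readers/writers and end-to-end orchestration.

#' Run configuration
#'
#' Collects every protocol constant in one place; the configuration is
#' echoed into every output for provenance. Defaults are the pipeline's
#' standard values: 20-px tumor threshold, 7 morphological clusters, top-50
#' attention tiles, 5 patch clusters, class weights 0.5/1.2, 5 folds,
#' 500 training epochs.
#'
#' @param ... overrides of the listed defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(pixel_pitch_mm = 0.064, min_tumor_px = 20L, k_morph = 7L,
              k_tiles = 50L, k_patch_clusters = 5L, w0 = 0.5, w1 = 1.2,
              folds = 5L, epochs = 500L, pretrain_epochs = 200L,
              lr = 1e-3, decay_rate = 9e-3, d_m = 64L, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a clinical case table
#'
#' Validates and filters a case-level CSV. Required columns: `case_id`,
#' `relapse_label`, `rfs_time_months`, `event`, `act_flag`, the 14
#' covariate columns, and optionally `n_slides`. Cases with any missing
#' covariate are excluded (reason `missing_covariate`); cases with fewer
#' than three slides are excluded in strict mode (reason `too_few_slides`)
#' and kept when `relax_slides = TRUE`.
#'
#' @param path CSV file path.
#' @param relax_slides keep cases with fewer than 3 slides (default FALSE).
#' @return List with `cases` (data frame), `clinical` (n x 14 matrix) and
#'   `excluded` (case_id, reason).
#' @export
read_cases <- function(path, relax_slides = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("case_id", "relapse_label", "rfs_time_months", "event",
           "act_flag", CLINICAL_NAMES)
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cases file lacks columns: ", paste(miss, collapse = ", "))
  excluded <- data.frame(case_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  bad_cov <- apply(df[, CLINICAL_NAMES], 1L, function(r) any(is.na(r)))
  if (any(bad_cov))
    excluded <- rbind(excluded,
                      data.frame(case_id = df$case_id[bad_cov],
                                 reason = "missing_covariate"))
  few <- if ("n_slides" %in% names(df) && !relax_slides)
    !is.na(df$n_slides) & df$n_slides < 3L else rep(FALSE, nrow(df))
  if (any(few & !bad_cov))
    excluded <- rbind(excluded,
                      data.frame(case_id = df$case_id[few & !bad_cov],
                                 reason = "too_few_slides"))
  keep <- !(bad_cov | few)
  bad_rows <- which(keep & (!df$relapse_label %in% c(0, 1) |
                              df$rfs_time_months <= 0 |
                              !df$event %in% c(0, 1)))
  if (length(bad_rows))
    stop("malformed rows for cases: ",
         paste(df$case_id[bad_rows], collapse = ", "))
  list(cases = df[keep, , drop = FALSE],
       clinical = as.matrix(df[keep, CLINICAL_NAMES]),
       excluded = excluded)
}

#' Write / read a case table with covariates
#'
#' @param cases case data frame (see [read_cases()] for the columns).
#' @param clinical n x 14 covariate matrix.
#' @param path CSV path.
#' @export
write_cases <- function(cases, clinical, path) {
  utils::write.csv(cbind(cases, as.data.frame(clinical)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read case-level spatial feature tables
#'
#' One row per case: `case_id` plus the 226 named registry columns.
#'
#' @param features matrix with registry column names (or a single named
#'   vector).
#' @param case_id case identifiers.
#' @param path CSV path.
#' @export
write_features <- function(features, case_id, path) {
  if (is.null(dim(features))) features <- matrix(features, 1L,
    dimnames = list(NULL, names(features)))
  stopifnot(identical(as.character(colnames(features)),
                      as.character(spatial_feature_registry())))
  utils::write.csv(data.frame(case_id = case_id, features,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  reg <- as.character(spatial_feature_registry())
  if (!identical(colnames(m), reg)) stop("feature columns do not match the registry")
  rownames(m) <- df$case_id
  m
}

#' End-to-end pipeline on a synthetic cohort
#'
#' Orchestrates synthesis, post-processing, feature construction, morph
#' bags, cross-validated training, ensemble thresholding, metrics and
#' grouped Shapley explanations, writing every artifact plus a manifest of
#' file hashes and the configuration echo to `out_dir`.
#'
#' @param synth a [synth_config()] for the cohort.
#' @param out_dir output directory (created if absent).
#' @param model model type for [fit_risk_model()].
#' @param epochs training epochs (default from the model spec).
#' @param seed protocol seed.
#' @return The manifest (invisibly), a named list of file hashes.
#' @export
pipeline_run <- function(synth, out_dir, model = "mvnet", epochs = 500L,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("synth", make_cohort(synth, keep_heatmaps = FALSE))
  stage("features",
        write_features(cohort$spatial, cohort$cases$case_id,
                       file.path(out_dir, "features.csv")))
  stage("cases",
        write_cases(cohort$cases, cohort$clinical,
                    file.path(out_dir, "cases.csv")))
  fit <- stage("train",
               fit_risk_model(cohort, model = model, seed = seed,
                              epochs = epochs))
  stage("predictions", {
    pred <- fit$stratification
    pred$fold <- fit$cv$folds
    utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  })
  stage("metrics",
        jsonlite::write_json(fit$metrics, file.path(out_dir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA))
  stage("explain", {
    baseline <- colMeans(cohort$spatial)
    f <- make_spatial_predictor(fit, cohort)
    rep1 <- shapley_spb(f, cohort$spatial[1L, ], baseline)
    utils::write.csv(data.frame(group = names(rep1$values),
                                value = rep1$values,
                                direction = rep1$direction),
                     file.path(out_dir, "attribution_case1.csv"),
                     row.names = FALSE)
  })
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(synth = unclass(synth)[
    !vapply(unclass(synth), is.matrix, TRUE)],
    model = model, epochs = epochs, seed = seed),
    cfg_path, auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Spatial-branch predictor closure for attribution
#'
#' Wraps a fitted risk model into a function mapping raw (unstandardized)
#' spatial feature rows to the ensemble relapse probability, holding the
#' morphological/clinical inputs of a reference case fixed. Used as the `f`
#' of [shapley_spb()].
#'
#' @param fit a `tls_risk_model`.
#' @param cohort the cohort the model was fitted on.
#' @param ref_case index of the case providing the fixed non-spatial
#'   inputs (default 1).
#' @return Function: matrix of 226-wide rows -> probability vector.
#' @export
make_spatial_predictor <- function(fit, cohort, ref_case = 1L) {
  models <- fit$cv$models
  function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
    n <- nrow(X)
    sub <- cohort
    sub$cases <- cohort$cases[rep(ref_case, n), , drop = FALSE]
    sub$spatial <- X
    sub$morph <- cohort$morph[rep(ref_case, n)]
    if (!is.null(cohort$clinical))
      sub$clinical <- cohort$clinical[rep(ref_case, n), , drop = FALSE]
    if (!is.null(cohort$bags)) sub$bags <- cohort$bags[rep(ref_case, n)]
    rowMeans(vapply(models, predict_one, numeric(n), cohort = sub))
  }
}
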