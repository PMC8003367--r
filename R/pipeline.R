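#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Unknown
#' keys are rejected; the configuration is fully serialisable (YAML/JSON).
#'
#' @param out_dir run directory (created if absent).
#' @param seed global RNG seed.
#' @param phantom named list of [phantom_spec()] arguments.
#' @param cohort named list of [cohort_spec()] arguments.
#' @param segmentation list: `tolerance` (DWI intensity units), `connectivity`.
#' @param model list: `type` (`"radsignature"`, `"radscore"` or `"fit"`), and
#'   for `"fit"` the controls `cp`, `minsplit`, `maxdepth`, `class_weights`.
#' @param evaluation list: `level`, `bootstrap_reps`, `train_fraction`.
#' @param write_volumes write phantom volumes/masks as NIfTI (default FALSE).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, phantom = list(), cohort = list(),
                            segmentation = list(tolerance = 40, connectivity = "face"),
                            model = list(type = "radsignature"),
                            evaluation = list(level = 0.95, bootstrap_reps = 200,
                                              train_fraction = 0.70),
                            write_volumes = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), phantom = phantom,
              cohort = cohort, segmentation = segmentation, model = model,
              evaluation = evaluation, write_volumes = isTRUE(write_volumes))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file holding the configuration keys.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

validate_pipeline_config <- function(cfg) {
  known <- c("out_dir", "seed", "phantom", "cohort", "segmentation", "model",
             "evaluation", "write_volumes")
  unknown <- setdiff(names(unclass(cfg)), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir)) stop("config needs `out_dir`")
  if (!cfg$model$type %in% c("radsignature", "radscore", "fit"))
    stop("model$type must be 'radsignature', 'radscore' or 'fit'")
  if (!is.null(cfg$segmentation$tolerance) && cfg$segmentation$tolerance < 0)
    stop("segmentation tolerance must be >= 0")
  invisible(cfg)
}

#' Write / read a feature table with the canonical 109-column schema
#'
#' Tables round-trip exactly; on read, feature columns are rearranged into
#' [feature_dictionary()] order (key columns first), and absent feature
#' columns raise an error.
#'
#' @param df data.frame of key columns plus feature columns.
#' @param path CSV path.
#' @param require_all error when canonical feature columns are missing
#'   (default TRUE on read).
#' @export
write_feature_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, require_all = TRUE) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dict <- feature_dictionary()
  missing <- setdiff(dict, names(df))
  if (require_all && length(missing))
    stop(sprintf("feature table missing %d canonical column(s), e.g. %s",
                 length(missing), missing[1]))
  keys <- setdiff(names(df), dict)
  df[c(keys, intersect(dict, names(df)))]
}

#' Run the full synthetic pipeline
#'
#' Chains the stages end to end: phantom simulation, seeded region-growing
#' segmentation of the phantom node on the DWI volume, 109-parameter feature
#' extraction from the co-registered ADC map, synthetic-cohort generation,
#' stratified patient-level train/test split, model application (fixed
#' printed rules) or CART fitting on the training regions, and
#' diagnostic-accuracy evaluation on region and patient bases. All artifacts
#' and a manifest (package version, seed, file checksums) are written under
#' `out_dir`; given the same configuration the metrics are byte-identical
#' across runs.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the run directory, the manifest, the
#'   feature vector, fitted/applied model, and evaluation tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- "phantom"
  res <- tryCatch({
    ## ---- phantom + segmentation + features --------------------------------
    pspec <- do.call(phantom_spec, c(config$phantom, list(seed = config$seed)))
    ph <- generate_phantom(pspec)
    if (config$write_volumes) {
      write_volume(ph$adc, out("phantom_adc.nii"))
      write_volume(ph$dwi, out("phantom_dwi.nii"))
      for (nm in names(ph$masks)) write_mask(ph$masks[[nm]], out(paste0("mask_", nm, ".nii")))
    }
    stage <- "segmentation"
    les <- pspec$lesions[[1]]
    seedvox <- pmin(pmax(round(les$center / pspec$spacing) + 1L, 1L), pspec$shape)
    seg <- region_grow(ph$dwi, seedvox,
                       tolerance = config$segmentation$tolerance %||% 40,
                       connectivity = config$segmentation$connectivity %||% "face")
    morph <- compute_morphometry(seg, pspec$spacing)
    stage <- "features"
    clinical <- list(histology = 0, grade = 2, tumor_size = 35, low_segment = 1,
                     deep_myometrial_invasion = 0, mr_ln_positive = 0, ca125 = 30)
    fv <- assemble_feature_vector(ph$adc, ph$masks$tumor, seg, ph$masks$bladder,
                                  morph, clinical)
    write_feature_table(cbind(data.frame(patient_id = "PHANTOM", region_id = "PHANTOM_L"),
                              as.data.frame(as.list(fv))),
                        out("phantom_features.csv"))

    ## ---- cohort + model + evaluation --------------------------------------
    stage <- "cohort"
    cspec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed + 1L)))
    cohort <- generate_cohort(cspec)
    utils::write.csv(cohort$patients, out("patients.csv"), row.names = FALSE)
    utils::write.csv(cohort$regions, out("regions.csv"), row.names = FALSE)

    stage <- "model"
    split <- split_train_test(cohort$patients,
                              fraction = config$evaluation$train_fraction %||% 0.70,
                              seed = config$seed + 2L)
    reg <- cohort$regions
    reg$set <- ifelse(reg$patient_id %in% split$train, "train", "test")
    model <- NULL
    if (config$model$type == "fit") {
      feats <- c("ADCt_mean", "ADCln_mean", "ADCln_skewness", "rADC_skewness",
                 "ln_short_axis", "ln_long_axis", "ln_mean_diameter",
                 "ln_axis_ratio", "ln_area")
      fml <- stats::as.formula(paste("label ~", paste(feats, collapse = " + ")))
      model <- fit_cart(fml, reg[reg$set == "train", ],
                        class_weights = config$model$class_weights %||% "inverse",
                        cp = config$model$cp %||% 0.01,
                        minsplit = config$model$minsplit %||% 5,
                        maxdepth = config$model$maxdepth %||% 4)
      reg$pred <- predict(model, reg)
    } else {
      rs <- predict(radscore_model(), reg)
      reg$pred <- if (config$model$type == "radscore") rs
                  else as.integer(rs == 1L & (reg$grade == 3 | reg$tumor_size >= 20))
      model <- radscore_model()
    }
    tree_to_json(model, out("model.json"))
    utils::write.csv(reg[c("patient_id", "region_id", "set", "label", "pred")],
                     out("predictions.csv"), row.names = FALSE)

    stage <- "evaluation"
    level <- config$evaluation$level %||% 0.95
    eval_rows <- list()
    for (s in c("train", "test")) {
      rr <- reg[reg$set == s, ]
      for (basis in c("region", "patient")) {
        d <- if (basis == "region") rr else aggregate_to_patient(rr, c("label", "pred"))
        cm <- confusion(d$pred, d$label)
        mt <- metrics_with_ci(cm, level)
        mt$set <- s; mt$basis <- basis
        mt$TP <- cm$TP; mt$TN <- cm$TN; mt$FP <- cm$FP; mt$FN <- cm$FN
        eval_rows[[paste(s, basis)]] <- mt
      }
    }
    metrics <- do.call(rbind, eval_rows)
    utils::write.csv(metrics, out("metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(split(metrics, paste(metrics$set, metrics$basis, sep = "_")),
             function(d) stats::setNames(as.list(d$estimate), d$metric)),
      out("metrics.json"), auto_unbox = TRUE, digits = 10)

    stage <- "manifest"
    files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
    manifest <- list(package = "lnradiomics",
                     version = as.character(utils::packageVersion("lnradiomics")),
                     seed = config$seed,
                     files = lapply(files, function(f)
                       list(name = f, md5 = unname(tools::md5sum(out(f))))))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
    list(out_dir = config$out_dir, manifest = manifest, features = fv,
         morphometry = morph, model = model, metrics = metrics,
         split = split, regions = reg)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
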