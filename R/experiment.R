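#' @title Experiment runner
#' @description Ties the pipeline stages into three reproducible
#'   experiments: `main` (train/evaluate on a familiar two-class cohort),
#'   `biased` (train and validate on internal-centre slides only, test on
#'   internal plus stain-shifted external slides, calibrate a variance
#'   threshold), and `unfamiliar` (compare uncertainty distributions of
#'   familiar test slides against out-of-distribution textures). A single
#'   master seed is fanned out deterministically per stage, so any re-run
#'   with the same configuration yields identical numeric reports.
#' @name cli-io
NULL

#' Experiment configuration
#'
#' Defaults describe the desk-scale synthetic world: 1200x1200 slides
#' (declared 0.49 um/pixel), three pyramid levels, training at level 0
#' with at most 6 tiles per slide, a 4-block classifier and 30
#' Monte-Carlo draws. All fields are echoed verbatim into every output
#' bundle (`config.json`).
#'
#' @param out_dir output bundle directory.
#' @param cohort_dir directory holding an existing cohort (`manifest.csv`
#'   plus pyramid directories); if `NULL`, a cohort is generated under
#'   `out_dir/cohort`.
#' @param n_per_class internal slides per class when generating.
#' @param base_size generated slide size in pixels.
#' @param n_levels pyramid levels per generated slide.
#' @param level resolution level used for tiling, training and diagnosis.
#' @param ring_contrast ring rendering contrast for generated cohorts.
#' @param ring_fraction_sd case-to-case difficulty spread (see
#'   [generate_cohort()]).
#' @param patch_size,min_tissue,max_patches tiling parameters (see
#'   [extract_patches()]).
#' @param model named list of [model_config()] overrides.
#' @param T Monte-Carlo dropout draws per patch.
#' @param keep_fraction internal keep fraction for variance-threshold
#'   calibration.
#' @param external_test_per_class stain-shifted external test slides per
#'   class (biased experiment).
#' @param n_ood out-of-distribution test slides (unfamiliar experiment).
#' @param shift [stain_shift()] applied to external slides.
#' @param seed master seed, fanned out per stage via [mix_seed()].
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, cohort_dir = NULL, n_per_class = 20L,
                       base_size = c(1200L, 1200L), n_levels = 3L,
                       level = 0L, ring_contrast = 0.6,
                       ring_fraction_sd = 0,
                       patch_size = 299L, min_tissue = 0.5,
                       max_patches = 6L, model = list(), T = 30L,
                       keep_fraction = 0.9, external_test_per_class = 4L,
                       n_ood = 6L, shift = stain_shift(), seed = 1L) {
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 n_per_class = as.integer(n_per_class),
                 base_size = as.integer(base_size),
                 n_levels = as.integer(n_levels), level = as.integer(level),
                 ring_contrast = ring_contrast,
                 ring_fraction_sd = ring_fraction_sd,
                 patch_size = as.integer(patch_size),
                 min_tissue = min_tissue,
                 max_patches = as.integer(max_patches),
                 model = model, T = as.integer(T),
                 keep_fraction = keep_fraction,
                 external_test_per_class = as.integer(external_test_per_class),
                 n_ood = as.integer(n_ood), shift = shift,
                 seed = as.integer(seed)),
            class = "run_config")
}

suq_log <- function(log_path, stage, msg) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
  invisible(line)
}

# stable CSV writer: fixed significant digits so reports are byte-identical
# across re-runs with the same seed
write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

tile_cohort <- function(manifest, cohort_dir, config, log) {
  sets <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pyr <- read_pyramid(file.path(cohort_dir, row$path),
                        levels = config$level)
    ps <- extract_patches(pyr, config$level, patch_size = config$patch_size,
                          min_tissue = config$min_tissue,
                          max_patches = config$max_patches,
                          seed = mix_seed(config$seed, "tile"))
    if (row$class_label %in% c("A", "B")) ps <- label_patches(ps, row$class_label)
    sets[[row$slide_id]] <- ps
  }
  log("tile", sprintf("tiled %d slide(s) at level %d", length(sets),
                      config$level))
  sets
}

diagnose_set <- function(model, sets, ids, config) {
  lapply(ids, function(id) {
    diagnose_slide(model, sets[[id]], T = config$T,
                   seed = mix_seed(config$seed, "predict", id))
  })
}

require_stratum <- function(manifest, what, rows) {
  if (sum(rows) == 0)
    stop("configuration error: cohort contains no ", what, " slides")
}

#' Run one experiment end to end
#'
#' See [run_config()] for the knobs. Every bundle contains `config.json`
#' (verbatim echo), `log.txt`, `manifest.csv`, `predictions.csv` and
#' `learning_curve.csv`; per experiment:
#' \describe{
#'   \item{main}{`roc.csv` (with the AUC), `rejection_global.csv`,
#'     `rejection_class_specific.csv`.}
#'   \item{biased}{`roc_internal.csv`, `roc_external.csv`,
#'     `ood_report.json`, `densities.csv` (internal validation vs external
#'     test uncertainty).}
#'   \item{unfamiliar}{`densities.csv` (familiar vs unfamiliar),
#'     `ood_report.json`, `rank_test.json` (one-sided rank test that
#'     unfamiliar uncertainties are larger).}
#' }
#'
#' @param config a [run_config()].
#' @param experiment `"main"`, `"biased"` or `"unfamiliar"`.
#' @return the report bundle as a list, invisibly (all files are written
#'   under `config$out_dir`).
#' @export
run_experiment <- function(config, experiment = c("main", "biased", "unfamiliar")) {
  stopifnot(inherits(config, "run_config"))
  experiment <- match.arg(experiment)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  if (file.exists(log_path)) unlink(log_path)
  log <- function(stage, msg) suq_log(log_path, stage, msg)
  echo <- unclass(config)
  echo$shift <- unclass(echo$shift)
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # --- cohort ---------------------------------------------------------
  cohort_dir <- config$cohort_dir
  if (is.null(cohort_dir)) {
    cohort_dir <- file.path(config$out_dir, "cohort")
    log("generate", sprintf("generating cohort (%d per class, contrast %.2f, seed %d)",
                            config$n_per_class, config$ring_contrast, config$seed))
    generate_cohort(
      n_per_class = config$n_per_class, seed = mix_seed(config$seed, "generate"),
      out_dir = cohort_dir, base_size = config$base_size,
      n_levels = config$n_levels, ring_contrast = config$ring_contrast,
      ring_fraction_sd = config$ring_fraction_sd,
      external_test_per_class =
        if (experiment == "biased") config$external_test_per_class else 0L,
      n_ood = if (experiment == "unfamiliar") config$n_ood else 0L,
      shift = config$shift)
  }
  manifest <- read_manifest(file.path(cohort_dir, "manifest.csv"))
  file.copy(file.path(cohort_dir, "manifest.csv"),
            file.path(config$out_dir, "manifest.csv"), overwrite = TRUE)

  # --- tiling ---------------------------------------------------------
  sets <- tile_cohort(manifest, cohort_dir, config, log)
  usable <- vapply(sets, length, 0L) > 0
  if (any(!usable))
    log("tile", sprintf("dropping %d no-tissue slide(s): %s", sum(!usable),
                        paste(names(sets)[!usable], collapse = ", ")))
  manifest <- manifest[usable[manifest$slide_id], , drop = FALSE]

  is_ab <- manifest$class_label %in% c("A", "B")
  is_int <- manifest$centre == "internal"
  require_stratum(manifest, "train-split", manifest$split == "train" & is_ab & is_int)
  require_stratum(manifest, "val-split", manifest$split == "val" & is_ab & is_int)
  require_stratum(manifest, "test-split", manifest$split == "test")
  if (experiment == "biased")
    require_stratum(manifest, "external-centre", manifest$centre == "external")
  if (experiment == "unfamiliar")
    require_stratum(manifest, "OOD", manifest$class_label == "OOD")

  ids <- function(cond) manifest$slide_id[cond]
  # training and validation always use internal A/B slides only
  train_ids <- ids(manifest$split == "train" & is_ab & is_int)
  val_ids <- ids(manifest$split == "val" & is_ab & is_int)

  # --- training -------------------------------------------------------
  mc <- do.call(model_config,
                modifyList(list(seed = mix_seed(config$seed, "model")),
                           config$model))
  model <- build_model(mc, level = config$level)
  log("train", sprintf("training on %d slide(s) / validating on %d",
                       length(train_ids), length(val_ids)))
  model <- train_model(model, sets[train_ids], sets[val_ids])
  write_report_csv(model$learning_curve,
                   file.path(config$out_dir, "learning_curve.csv"))
  log("train", sprintf("final validation accuracy %.3f",
                       tail(model$learning_curve$val_accuracy, 1)))

  # --- prediction -----------------------------------------------------
  truth <- stats::setNames(manifest$class_label, manifest$slide_id)
  test_ids <- ids(manifest$split == "test" & is_ab)
  log("predict", sprintf("Monte-Carlo diagnosis (T = %d)", config$T))
  diag_test <- diagnose_set(model, sets, test_ids, config)
  dt <- diagnosis_table(diag_test)
  dt$centre <- manifest$centre[match(dt$slide_id, manifest$slide_id)]
  dt$truth <- unname(truth[dt$slide_id])
  write_report_csv(dt, file.path(config$out_dir, "predictions.csv"))

  bundle <- list(config = config, experiment = experiment, model = model,
                 manifest = manifest, diagnoses = diag_test, truth = truth)

  if (experiment == "main") {
    roc <- roc_auc(dt$mu_slide, dt$truth)
    rej_g <- rejection_curve(diag_test, truth, metric = "auc", mode = "global")
    rej_c <- rejection_curve(diag_test, truth, metric = "accuracy",
                             mode = "class_specific")
    roc_df <- roc$points
    roc_df$auc <- roc$auc
    write_report_csv(roc_df, file.path(config$out_dir, "roc.csv"))
    write_report_csv(rej_g$points,
                     file.path(config$out_dir, "rejection_global.csv"))
    write_report_csv(rej_c$points,
                     file.path(config$out_dir, "rejection_class_specific.csv"))
    log("evaluate", sprintf("test AUC = %.4f over %d slide(s)", roc$auc,
                            nrow(dt)))
    bundle$roc <- roc
    bundle$rejection_global <- rej_g
    bundle$rejection_class_specific <- rej_c
  } else if (experiment == "biased") {
    diag_val <- diagnose_set(model, sets, val_ids, config)
    dv <- diagnosis_table(diag_val)
    int_ids <- dt$slide_id[dt$centre == "internal"]
    ext_ids <- dt$slide_id[dt$centre == "external"]
    roc_int <- roc_auc(dt$mu_slide[dt$slide_id %in% int_ids],
                       dt$truth[dt$slide_id %in% int_ids])
    roc_ext <- roc_auc(dt$mu_slide[dt$slide_id %in% ext_ids],
                       dt$truth[dt$slide_id %in% ext_ids])
    rep <- ood_report(dv$sigma_slide,
                      dt$sigma_slide[dt$slide_id %in% ext_ids],
                      keep_fraction = config$keep_fraction)
    dens <- uncertainty_density(list(
      internal_validation = dv$sigma_slide,
      external_test = dt$sigma_slide[dt$slide_id %in% ext_ids]))
    write_roc <- function(r, f) {
      p <- r$points; p$auc <- r$auc
      write_report_csv(p, file.path(config$out_dir, f))
    }
    write_roc(roc_int, "roc_internal.csv")
    write_roc(roc_ext, "roc_external.csv")
    jsonlite::write_json(unclass(rep),
                         file.path(config$out_dir, "ood_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_density_csv(dens, file.path(config$out_dir, "densities.csv"))
    log("evaluate", sprintf("internal AUC %.3f, external AUC %.3f; t = %.4g rejects %.0f%% external",
                            roc_int$auc, roc_ext$auc, rep$threshold,
                            100 * rep$ood_rejected_fraction))
    bundle$roc_internal <- roc_int
    bundle$roc_external <- roc_ext
    bundle$ood_report <- rep
    bundle$densities <- dens
    bundle$diagnoses_val <- diag_val
  } else { # unfamiliar
    ood_ids <- ids(manifest$class_label == "OOD")
    diag_val <- diagnose_set(model, sets, val_ids, config)
    diag_ood <- diagnose_set(model, sets, ood_ids, config)
    dv <- diagnosis_table(diag_val)
    do <- diagnosis_table(diag_ood)
    rep <- ood_report(dv$sigma_slide, do$sigma_slide,
                      keep_fraction = config$keep_fraction)
    dens <- uncertainty_density(list(familiar_test = dt$sigma_slide,
                                     unfamiliar = do$sigma_slide))
    rt <- wilcox.test(do$sigma_slide, dt$sigma_slide,
                      alternative = "greater", exact = FALSE)
    jsonlite::write_json(unclass(rep),
                         file.path(config$out_dir, "ood_report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(statistic = unname(rt$statistic),
                              p_value = rt$p.value,
                              alternative = "unfamiliar sigma stochastically larger"),
                         file.path(config$out_dir, "rank_test.json"),
                         auto_unbox = TRUE, digits = NA)
    write_density_csv(dens, file.path(config$out_dir, "densities.csv"))
    log("evaluate", sprintf("t = %.4g rejects %.0f%% of unfamiliar slides (rank test p = %.3g)",
                            rep$threshold, 100 * rep$ood_rejected_fraction,
                            rt$p.value))
    bundle$ood_report <- rep
    bundle$densities <- dens
    bundle$rank_test <- rt
    bundle$diagnoses_ood <- diag_ood
    bundle$diagnoses_val <- diag_val
  }
  log("done", sprintf("bundle written to %s", config$out_dir))
  invisible(bundle)
}

write_density_csv <- function(dens, path) {
  df <- data.frame(sigma = dens$grid)
  for (g in names(dens$density)) df[[g]] <- dens$density[[g]]
  write_report_csv(df, path)
}
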