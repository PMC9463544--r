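#' Validate a run configuration
#'
#' Reads a JSON run configuration (or takes an equivalent list), checks it
#' against the platform schema with strict unknown-key rejection, and fills
#' the documented defaults: Savitzky-Golay order 2 / window 41, match point
#' 1000 nm, confidence z 1.96, classifier penalty 0.1, probe defaults, and
#' the 500-1500 nm grid. A seed is mandatory because every stage downstream
#' of it is stochastic.
#'
#' @param config Path to a JSON file or a named list.
#' @return An `ewdrs_run_config` (validated, defaults filled).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_ewdrs(paste("config file not found:", config), "ewdrs_validation")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(
    stages = c("synth", "classify"),
    seed = NULL,
    grid_nm = list(from = 500, to = 1500, by = 25),
    photons_per_wavelength = 20000,
    probe = list(core_radius_mm = 0.3, na = 0.39, spacing_mm = 0.66,
                 n_detectors = 6),
    preprocessing = list(sg_order = 2, sg_window = 41, match_nm = 1000),
    analysis = list(z = 1.96),
    classifier = list(lambda = 0.1),
    classes = c("nerve", "nvb", "skin", "muscle", "vessel", "connective"),
    n_per_class = 5,
    output_dir = NULL)
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  for (k in c("probe", "preprocessing", "analysis", "classifier", "grid_nm")) {
    if (!is.null(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad))
        problems <- c(problems, sprintf("unknown key(s) in %s: %s", k,
                                        paste(bad, collapse = ", ")))
      config[[k]] <- modifyList(defaults[[k]], config[[k]])
    }
  }
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || cfg$seed < 0)
    problems <- c(problems, "seed: a non-negative integer seed is mandatory")
  if (!is.numeric(cfg$photons_per_wavelength) || cfg$photons_per_wavelength < 1)
    problems <- c(problems, "photons_per_wavelength: must be a positive count")
  if (!is.numeric(cfg$n_per_class) || cfg$n_per_class < 2)
    problems <- c(problems, "n_per_class: must be at least 2")
  if (cfg$preprocessing$sg_window %% 2 == 0 ||
      cfg$preprocessing$sg_window <= cfg$preprocessing$sg_order)
    problems <- c(problems, "preprocessing: sg_window must be odd and > sg_order")
  if (cfg$analysis$z < 0) problems <- c(problems, "analysis.z: must be >= 0")
  if (cfg$classifier$lambda < 0) problems <- c(problems, "classifier.lambda: must be >= 0")
  bad_stage <- setdiff(cfg$stages, c("synth", "simulate", "compare", "classify"))
  if (length(bad_stage))
    problems <- c(problems, paste("unknown stage(s):", paste(bad_stage, collapse = ", ")))
  if (length(problems))
    stop_ewdrs(paste0("invalid configuration:\n  - ",
                      paste(problems, collapse = "\n  - ")), "ewdrs_validation")
  structure(cfg, class = "ewdrs_run_config")
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order — `synth` (phantom study
#' spectra), `simulate` (per-phantom simulated spectra), `compare`
#' (agreement of each phantom's simulated spectrum against the confidence
#' band of its synthetic repeats), `classify` (labeled tissue dataset,
#' LOOCV, confusion summary) — writing every output as CSV/JSON under
#' `output_dir` together with a manifest of paths, MD5 hashes, and the seed
#' record. Reruns with the same configuration and seed produce
#' bit-identical outputs.
#'
#' @param config An [validate_config()] result (or something it accepts).
#' @return The manifest (data frame of stage, file, md5), invisibly;
#'   also written to `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$output_dir
  if (is.null(out_dir))
    stop_ewdrs("output_dir is required to run the pipeline", "ewdrs_validation")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- do.call(probe_geometry, cfg$probe)
  grid <- seq(cfg$grid_nm$from, cfg$grid_nm$to, by = cfg$grid_nm$by)
  files <- character(0)
  stage_of <- character(0)
  emit <- function(stage, name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    stage_of <<- c(stage_of, stage)
  }
  study <- NULL
  if (any(c("synth", "simulate", "compare") %in% cfg$stages)) {
    study <- make_phantom_study(cfg$seed, probe, grid,
                                cfg$photons_per_wavelength)
  }
  if ("synth" %in% cfg$stages) {
    for (i in seq_along(study$spectra)) {
      nm <- sprintf("synth_%s_rep%d.csv", study$manifest$phantom[i],
                    study$manifest$repeat_idx[i])
      emit("synth", nm, function(p) write_spectrum_csv(study$spectra[[i]], p))
    }
  }
  if ("simulate" %in% cfg$stages) {
    for (id in names(study$true_spectra))
      emit("simulate", sprintf("sim_%s.csv", id), local({
        s <- study$true_spectra[[id]]
        function(p) write_spectrum_csv(s, p)
      }))
  }
  if ("compare" %in% cfg$stages) {
    reports <- list()
    for (id in unique(study$manifest$phantom)) {
      reps <- lapply(study$spectra[study$manifest$phantom == id], auc_normalize)
      band <- confidence_band(reps, z = cfg$analysis$z)
      agr <- agreement(auc_normalize(study$true_spectra[[id]]), band)
      reports[[id]] <- list(
        out_of_band_intervals = agr$intervals,
        visnir_ratio = peak_ratio_phantom_vis(study$true_spectra[[id]]),
        swir_ratio = peak_ratio_swir(study$true_spectra[[id]]))
    }
    emit("compare", "agreement_report.json", function(p)
      jsonlite::write_json(reports, p, auto_unbox = TRUE, digits = NA))
  }
  if ("classify" %in% cfg$stages) {
    ds <- make_labeled_dataset(cfg$classes, cfg$n_per_class, probe, grid,
                               cfg$photons_per_wavelength, seed = cfg$seed)
    feats <- prepare_features(ds$spectra, ds$labels, band = "full")
    pred <- loocv(feats, prior_scale = cfg$classifier$lambda)
    conf <- confusion_and_accuracy(feats$labels, pred)
    emit("classify", "classification.json", function(p)
      jsonlite::write_json(list(accuracy = conf$accuracy,
                                misclassified = conf$misclassified,
                                confusion = as.data.frame(conf$table),
                                seed = cfg$seed),
                           p, auto_unbox = TRUE, digits = NA))
  }
  manifest <- data.frame(stage = stage_of, file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(list(seed = cfg$seed, stages = cfg$stages,
                            outputs = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
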