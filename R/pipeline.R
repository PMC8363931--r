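FIBRO_MARKERS <- c("PDGFRA", "PDGFRB", "aSMA", "FAP", "SPARC", "POSTN",
                   "COL1")
ROUND1_MARKERS <- c("PDGFRA", "PDGFRB", "aSMA", "FAP")
ROUND2_MARKERS <- c("SPARC", "POSTN", "COL1")

#' Pipeline run configuration
#'
#' One home for every tunable of a simulate -> register/QC -> segment ->
#' zones -> quantify -> survive run. Serializes losslessly to YAML via
#' [yaml::as.yaml()].
#'
#' @param n_patients,cores_per_patient cohort size of the simulated study
#' @param beta injected log hazard ratio per scaled unit of
#'   `effect_variable`
#' @param effect_variable variable carrying the survival effect, e.g.
#'   `"PDGFRB_meso"`
#' @param baseline_hazard,censor_rate survival-time generator settings
#' @param core_diameter_um,pixel_size_um,noise_sd phantom raster and noise
#' @param zone_width_um,n_zones stromal distance-zone geometry
#' @param tumor_threshold tumor-marker threshold (`NULL` = Otsu per core)
#' @param positivity_threshold,confidence_threshold positive-area settings
#' @param min_tissue_fraction QC threshold on the tissue fraction of the
#'   core disc
#' @param max_shift_um registration search radius
#' @param m Bonferroni family size (`NULL` = number of screened variables)
#' @param adjusters clinical covariates of the multivariable models
#' @param multivariable_sets list of variable sets for adjusted models
#' @param classifier_trees random-forest size for the masking classifier
#' @param train_cores number of cores contributing pooled training pixels
#' @param write_images write per-core TIFF bundles into the run directory?
#' @param seed run seed; per-stage seeds derive from it via [stage_seed()]
#' @param out_dir run directory (`NULL` = in-memory run, nothing written)
#' @export
run_config <- function(n_patients = 24, cores_per_patient = 2,
                       beta = 0, effect_variable = "PDGFRB_meso",
                       baseline_hazard = 0.02, censor_rate = 0.04,
                       core_diameter_um = 1000, pixel_size_um = 8,
                       noise_sd = 0.02,
                       zone_width_um = 12, n_zones = 4,
                       tumor_threshold = NULL,
                       positivity_threshold = NULL,
                       confidence_threshold = 0.85,
                       min_tissue_fraction = 0.1, max_shift_um = 50,
                       m = NULL,
                       adjusters = c("age", "sex", "side", "stage",
                                     "histology"),
                       multivariable_sets = list(),
                       classifier_trees = 50L, train_cores = 8L,
                       write_images = FALSE, seed = 1L, out_dir = NULL) {
  cfg <- list(n_patients = n_patients, cores_per_patient = cores_per_patient,
              beta = beta, effect_variable = effect_variable,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              core_diameter_um = core_diameter_um,
              pixel_size_um = pixel_size_um, noise_sd = noise_sd,
              zone_width_um = zone_width_um, n_zones = n_zones,
              tumor_threshold = tumor_threshold,
              positivity_threshold = positivity_threshold,
              confidence_threshold = confidence_threshold,
              min_tissue_fraction = min_tissue_fraction,
              max_shift_um = max_shift_um, m = m, adjusters = adjusters,
              multivariable_sets = multivariable_sets,
              classifier_trees = classifier_trees, train_cores = train_cores,
              write_images = write_images, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file mirroring the [run_config()] fields
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL # the run's identity is its parameters, not its location
  fnv1a_hex(yaml::as.yaml(cfg))
}

# per-patient raw marker truth: independent meso and stroma mean levels per
# fibroblast marker
draw_marker_truth <- function(n_patients, markers = FIBRO_MARKERS) {
  vars <- as.vector(outer(markers, c("meso", "stroma"), paste, sep = "_"))
  truth <- matrix(stats::rbeta(n_patients * length(vars), 2, 18),
                  n_patients, length(vars), dimnames = list(NULL, vars))
  truth
}

core_channel_models <- function(truth_row, noise_free_baseline = 0.02) {
  mods <- list(
    DAPI = channel_model(0.02, c(tumor = 0.5, stroma = 0.35, vessel = 0.3,
                                 autofluorescence = 0.7), round_id = "r1"),
    CK5 = channel_model(0.02, c(tumor = 0.55, stroma = 0.05, vessel = 0.05,
                                autofluorescence = 0.6), round_id = "r1"))
  for (mk in ROUND1_MARKERS) {
    mods[[mk]] <- channel_model(
      noise_free_baseline,
      c(tumor = truth_row[[paste0(mk, "_meso")]],
        stroma = truth_row[[paste0(mk, "_stroma")]],
        vessel = 0.1, autofluorescence = 0.7), round_id = "r1")
  }
  mods$DAPI2 <- channel_model(0.02, c(tumor = 0.5, stroma = 0.35,
                                      vessel = 0.3,
                                      autofluorescence = 0.7),
                              round_id = "r2")
  mods$CKMIX <- channel_model(0.02, c(tumor = 0.55, stroma = 0.05,
                                      vessel = 0.05,
                                      autofluorescence = 0.6),
                              round_id = "r2")
  for (mk in ROUND2_MARKERS) {
    mods[[mk]] <- channel_model(
      noise_free_baseline,
      c(tumor = truth_row[[paste0(mk, "_meso")]],
        stroma = truth_row[[paste0(mk, "_stroma")]],
        vessel = 0.1, autofluorescence = 0.7), round_id = "r2")
  }
  mods
}

random_core_geometry <- function(core_diameter_um) {
  R <- core_diameter_um / 2
  n_tum <- sample(2:3, 1)
  tumor <- lapply(seq_len(n_tum), function(i) {
    disc(stats::runif(2, -0.5 * R, 0.5 * R), stats::runif(1, 0.2 * R,
                                                          0.45 * R))
  })
  n_ves <- sample(2:4, 1)
  vessel <- lapply(seq_len(n_ves), function(i) {
    disc(stats::runif(2, -0.8 * R, 0.8 * R), stats::runif(1, 20, 40))
  })
  debris <- if (stats::runif(1) < 0.3) {
    list(disc(stats::runif(2, -0.8 * R, 0.8 * R), stats::runif(1, 10, 30)))
  } else list()
  list(tumor = tumor, vessel = vessel, debris = debris)
}

# split a rendered stack into the two staining rounds, displacing round 2 by
# an integer pixel shift (what registration must undo)
split_into_rounds <- function(image, truth, shift) {
  r1_names <- names(which(image$round_id == "r1"))
  r2_names <- names(which(image$round_id == "r2"))
  round1 <- multiplex_image(image$channels[r1_names], image$pixel_size_um,
                            core_id = image$core_id,
                            patient_id = image$patient_id,
                            round_id = image$round_id[r1_names])
  ch2 <- lapply(image$channels[r2_names], function(ch) {
    out <- translate_matrix(ch, shift[1], shift[2])
    attr(out, "invalid") <- NULL
    out
  })
  names(ch2)[names(ch2) == "DAPI2"] <- "DAPI" # shared counterstain name
  rid2 <- stats::setNames(rep("r2", length(ch2)), names(ch2))
  round2 <- multiplex_image(ch2, image$pixel_size_um,
                            core_id = image$core_id,
                            patient_id = image$patient_id, round_id = rid2)
  list(round1 = round1, round2 = round2, shift = shift)
}

#' Simulate a full multiplexed-IHC study
#'
#' Generates a cohort whose death hazard depends log-linearly on one chosen
#' marker variable, plus two-round core-image pairs per patient whose channel
#' intensities encode each patient's per-marker compartment means. Every
#' core carries exact ground truth.
#'
#' @param config a [run_config()]
#' @return list: `cohort`, `truth` (patients x marker-by-compartment raw
#'   means), `expected_table` (what an ideal measurement would report,
#'   baseline included), `cores` (per core: round1, round2, shift, truth)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(stage_seed(config$seed, "simulate"))
  truth <- draw_marker_truth(config$n_patients)
  effect <- if (config$effect_variable %in% colnames(truth)) {
    truth[, config$effect_variable]
  } else stop("effect_variable not among simulated variables", call. = FALSE)

  cohort <- generate_cohort(
    cohort_spec(config$n_patients, beta = config$beta,
                baseline_hazard = config$baseline_hazard,
                censor_rate = config$censor_rate,
                seed = stage_seed(config$seed, "cohort")),
    marker_values = effect)

  max_shift_px <- max(1L, as.integer(
    floor(config$max_shift_um / config$pixel_size_um)) - 1L)
  shift_amp <- min(2L, max_shift_px)
  cores <- list()
  set.seed(stage_seed(config$seed, "geometry"))
  for (p in seq_len(config$n_patients)) {
    for (k in seq_len(config$cores_per_patient)) {
      core_id <- sprintf("%s_c%d", cohort$patient_id[p], k)
      geo <- random_core_geometry(config$core_diameter_um)
      shift <- sample(-shift_amp:shift_amp, 2, replace = TRUE)
      spec <- phantom_spec(
        core_diameter_um = config$core_diameter_um,
        pixel_size_um = config$pixel_size_um,
        tumor_shapes = geo$tumor, vessel_shapes = geo$vessel,
        debris_shapes = geo$debris,
        channel_models = core_channel_models(as.list(truth[p, ])),
        noise_sd = config$noise_sd,
        seed = stage_seed(config$seed, paste0("render_", core_id)))
      ph <- generate_core_phantom(spec, zone_truth = FALSE)
      ph$image$core_id <- core_id
      ph$image$patient_id <- cohort$patient_id[p]
      cores[[core_id]] <- c(split_into_rounds(ph$image, ph$truth, shift),
                            list(truth = ph$truth))
    }
  }

  expected <- truth + 0.02 # channel baseline shifts every measured mean
  zone_vars <- as.vector(outer(FIBRO_MARKERS,
                               c(paste0("meso_Z", 1:4),
                                 paste0("vessel_Z", 1:4)), paste, sep = "_"))
  expected_table <- cbind(expected,
                          matrix(expected[, paste0(FIBRO_MARKERS, "_stroma")][
                            , rep(seq_along(FIBRO_MARKERS), 8)],
                            nrow = config$n_patients,
                            dimnames = list(NULL, zone_vars)))
  list(cohort = cohort, truth = truth, expected_table = expected_table,
       cores = cores)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> register/QC -> mask -> segment -> zones ->
#' quantify -> survive as one reproducible run. A single run seed fans out to
#' per-stage seeds by stage-name hashing, so re-running an identical config
#' reproduces every numeric output bit for bit. When `config$out_dir` is
#' set, tables, reports, logs and a provenance manifest (config hash
#' included) are written there; a pre-existing run directory with a
#' different config hash is refused.
#'
#' @param config a [run_config()]
#' @param study optional pre-simulated [simulate_study()] result to reuse
#' @return list: `cohort`, `qc`, `patient_table`, `scaled_table`, `screen`,
#'   `positivity`, `study`, `config`, `hash`
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[mesozone] ", line)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    prov_path <- file.path(out_dir, "provenance.json")
    if (file.exists(prov_path)) {
      prev <- jsonlite::read_json(prov_path)
      if (!identical(prev$config_hash, hash)) {
        stop("run directory holds a different config (hash mismatch); ",
             "refusing to resume", call. = FALSE)
      }
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  logf("run %s: seed %d, %d patients x %d cores", hash, config$seed,
       config$n_patients, config$cores_per_patient)
  if (is.null(study)) study <- simulate_study(config)
  zcfg <- zone_config(config$zone_width_um, config$n_zones)

  if (!is.null(out_dir) && config$write_images) {
    for (r in c("round1", "round2")) {
      write_fixture_bundle(
        file.path(out_dir, r),
        lapply(study$cores, `[[`, r),
        cohort = if (r == "round1") study$cohort)
    }
  }

  # one classifier per run, trained on ground-truth-labeled pixels pooled
  # across several cores so it learns masking cues that generalize across
  # patients' marker levels (the analogue of scribbling on multiple spots)
  n_train_cores <- min(config$train_cores, length(study$cores))
  train_ids <- names(study$cores)[unique(round(seq(
    1, length(study$cores), length.out = n_train_cores)))]
  feats <- list(); labs <- list()
  for (tid in train_ids) {
    core <- study$cores[[tid]]
    regt <- register_rounds(core$round1, core$round2, "DAPI",
                            config$max_shift_um)
    tr <- sample_training_pixels(
      regt$fused,
      c(core$truth$masks["autofluorescence"], core$truth$masks["vessel"],
        core$truth$masks["background"],
        list(tissue = core$truth$compartments$tumor |
               core$truth$compartments$stroma)),
      n_per_class = 150L,
      seed = stage_seed(config$seed, paste0("train_", tid)))
    feats[[tid]] <- tr$features; labs[[tid]] <- as.character(tr$labels)
  }
  classifier <- train_pixel_classifier(do.call(rbind, feats),
                                       unlist(labs),
                                       seed = stage_seed(config$seed,
                                                         "forest"),
                                       num_trees = config$classifier_trees)
  logf("classifier trained on %d labeled pixels from %d cores",
       length(unlist(labs)), length(train_ids))

  qc_rows <- list(); meas <- list(); posit <- list()
  for (core_id in names(study$cores)) {
    core <- study$cores[[core_id]]
    reg <- tryCatch(register_rounds(core$round1, core$round2, "DAPI",
                                    config$max_shift_um),
                    error = function(e) e)
    if (inherits(reg, "error")) {
      qc_rows[[core_id]] <- data.frame(
        core_id = core_id, tissue_fraction = NA_real_, shift_y_um = NA_real_,
        shift_x_um = NA_real_, passed = FALSE,
        reasons = conditionMessage(reg), stringsAsFactors = FALSE)
      logf("core %s failed registration: %s", core_id,
           conditionMessage(reg))
      next
    }
    masks <- classify_pixels(reg$fused, classifier)
    qc <- qc_core(reg$fused, masks$masks$tissue,
                  config$min_tissue_fraction, registration_ok = TRUE,
                  shift_um = reg$shift_um)
    qc_rows[[core_id]] <- data.frame(
      core_id = core_id, tissue_fraction = qc$tissue_fraction,
      shift_y_um = reg$shift_um[1], shift_x_um = reg$shift_um[2],
      passed = qc$passed,
      reasons = paste(qc$reasons, collapse = "; "), stringsAsFactors = FALSE)
    if (!qc$passed) {
      logf("core %s failed QC: %s", core_id,
           paste(qc$reasons, collapse = "; "))
      next
    }
    comp <- segment_components(reg$fused, masks, c("CK5", "CKMIX"),
                               tumor_threshold = config$tumor_threshold)
    zm <- compute_zones(comp$labels == 1L, comp$labels == 2L, zcfg,
                        reg$fused$pixel_size_um, "meso")
    zv <- compute_zones(comp$labels == 3L, comp$labels == 2L, zcfg,
                        reg$fused$pixel_size_um, "vessel")
    meas[[core_id]] <- measure_core(reg$fused, comp, zm, zv, FIBRO_MARKERS)
    posit[[core_id]] <- tryCatch(
      classify_tumor_positivity(reg$fused, comp, "PDGFRB",
                                config$positivity_threshold,
                                config$confidence_threshold),
      error = function(e) NULL)
  }
  qc_table <- do.call(rbind, qc_rows)
  passed <- qc_table$core_id[qc_table$passed]
  logf("%d/%d cores passed QC", length(passed), nrow(qc_table))

  measurements <- do.call(rbind, meas)
  patient_table <- build_patient_table(measurements, passed_cores = passed)
  scaled <- scale_for_cox(patient_table)
  positivity <- if (length(posit)) {
    aggregate_positivity(Filter(Negate(is.null), posit))
  }

  screen <- run_screen(scaled, study$cohort,
                       multivariable_sets = config$multivariable_sets,
                       adjusters = config$adjusters, m = config$m)
  logf("screen: %d variables, Bonferroni m = %d, top variable %s",
       nrow(screen$univariate), screen$m, screen$report$variable[1])

  if (!is.null(out_dir)) {
    utils::write.csv(qc_table, file.path(out_dir, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(patient_table, file.path(out_dir, "patient_table.csv"),
                     row.names = FALSE)
    utils::write.csv(screen$report, file.path(out_dir, "screen_report.csv"),
                     row.names = FALSE)
    if (!is.null(positivity)) {
      utils::write.csv(positivity, file.path(out_dir, "positivity.csv"),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           config = unclass(config),
           outputs = c("qc.csv", "patient_table.csv", "screen_report.csv",
                       if (!is.null(positivity)) "positivity.csv",
                       "run.log"),
           n_cores = nrow(qc_table), n_passed = length(passed),
           package_version = as.character(utils::packageVersion("mesozone"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, null = "null")
  }

  list(cohort = study$cohort, qc = qc_table, patient_table = patient_table,
       scaled_table = scaled, screen = screen, positivity = positivity,
       study = study, config = config, hash = hash)
}
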