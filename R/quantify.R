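COMPARTMENT_VARS <- c("meso", "stroma",
                      paste0("meso_Z", 1:4), paste0("vessel_Z", 1:4))

#' Mean intensity over a mask
#'
#' Arithmetic mean of a channel over mask pixels — the "mean intensity"
#' (a.k.a. expression) measure. An empty mask yields `NA` (missing), never 0.
#'
#' @param channel numeric matrix
#' @param mask logical matrix, same shape
#' @param invalid optional logical matrix of pixels to exclude
#' @export
mean_intensity <- function(channel, mask, invalid = NULL) {
  stop_if_not_same_shape(channel, mask, "channel and mask")
  if (!is.null(invalid)) mask <- mask & !invalid
  masked_mean(channel, mask)
}

#' Measure marker mean intensities of one core in all compartments
#'
#' For each marker channel, measures mean intensity in the mesothelioma
#' compartment (`meso`), total stroma (`stroma`), and the meso/vessel
#' distance zones 1..n. Invalid pixels are excluded everywhere.
#'
#' @param image a [multiplex_image()]
#' @param compartments a `compartment_map` from [segment_components()]
#' @param zones_meso,zones_vessel `zone_map`s over the stroma from
#'   [compute_zones()]
#' @param markers channel names to quantify (default: all channels)
#' @return long data.frame: patient_id, core_id, marker, compartment,
#'   mean_intensity, pixel_count
#' @export
measure_core <- function(image, compartments, zones_meso, zones_vessel,
                         markers = names(image$channels)) {
  stopifnot(inherits(image, "multiplex_image"),
            inherits(compartments, "compartment_map"))
  lab <- compartments$labels
  invalid <- image$invalid %||% matrix(FALSE, nrow(lab), ncol(lab))
  region_masks <- c(
    list(meso = lab == 1L & !invalid, stroma = lab == 2L & !invalid),
    stats::setNames(lapply(1:zones_meso$config$n_zones, function(k) {
      zones_meso$labels == k & !invalid
    }), paste0("meso_Z", 1:zones_meso$config$n_zones)),
    stats::setNames(lapply(1:zones_vessel$config$n_zones, function(k) {
      zones_vessel$labels == k & !invalid
    }), paste0("vessel_Z", 1:zones_vessel$config$n_zones)))
  rows <- expand.grid(marker = markers, compartment = names(region_masks),
                      stringsAsFactors = FALSE)
  rows$mean_intensity <- mapply(function(m, r) {
    masked_mean(image$channels[[m]], region_masks[[r]])
  }, rows$marker, rows$compartment)
  rows$pixel_count <- vapply(rows$compartment,
                             function(r) sum(region_masks[[r]]), integer(1))
  data.frame(patient_id = image$patient_id, core_id = image$core_id, rows,
             stringsAsFactors = FALSE)
}

#' Build the per-patient variable table
#'
#' Aggregates core-level mean intensities into per-patient "average mean
#' intensity" variables named `<MARKER>_<compartment>`, one column per
#' marker-by-compartment pair, by arithmetic mean over each patient's
#' QC-passed cores. Patients without any passed core are dropped with a
#' message.
#'
#' @param measurements row-bound output of [measure_core()] across cores
#' @param passed_cores optional character vector of core_ids that passed QC
#'   (default: all cores present)
#' @return wide data.frame (rows = patients, columns = variables), raw
#'   intensity scale recorded in `attr(, "scale")`; per-cell contributing
#'   core counts in `attr(, "n_cores")`
#' @export
build_patient_table <- function(measurements, passed_cores = NULL) {
  need <- c("patient_id", "core_id", "marker", "compartment",
            "mean_intensity")
  stopifnot(all(need %in% names(measurements)))
  if (anyDuplicated(measurements[c("patient_id", "core_id", "marker",
                                   "compartment")])) {
    stop("duplicate (patient, core) measurement keys", call. = FALSE)
  }
  all_patients <- unique(measurements$patient_id)
  if (!is.null(passed_cores)) {
    measurements <- measurements[measurements$core_id %in% passed_cores, ]
  }
  dropped <- setdiff(all_patients, unique(measurements$patient_id))
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " patient(s) with no QC-passed core: ",
            paste(dropped, collapse = ", "))
  }
  measurements$variable <- paste(measurements$marker,
                                 measurements$compartment, sep = "_")
  vars <- unique(measurements$variable)
  patients <- unique(measurements$patient_id)
  tab <- matrix(NA_real_, length(patients), length(vars),
                dimnames = list(patients, vars))
  ncore <- matrix(0L, length(patients), length(vars),
                  dimnames = list(patients, vars))
  sp <- split(measurements, measurements[c("variable", "patient_id")],
              drop = TRUE)
  for (chunk in sp) {
    v <- chunk$mean_intensity[!is.na(chunk$mean_intensity)]
    tab[chunk$patient_id[1], chunk$variable[1]] <-
      if (length(v)) mean(v) else NA_real_
    ncore[chunk$patient_id[1], chunk$variable[1]] <- length(v)
  }
  out <- data.frame(patient_id = patients, tab, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scale") <- "raw"
  attr(out, "n_cores") <- ncore
  out
}

#' Scale intensity variables for Cox regression
#'
#' Multiplies every intensity variable by 1,000 so hazard ratios per unit are
#' on a readable scale. Refuses to scale twice.
#'
#' @param table a [build_patient_table()] result
#' @export
scale_for_cox <- function(table) {
  if (identical(attr(table, "scale"), "x1000")) {
    stop("table is already on the x1000 scale", call. = FALSE)
  }
  num <- setdiff(names(table), "patient_id")
  table[num] <- lapply(table[num], function(x) x * 1000)
  attr(table, "scale") <- "x1000"
  table
}

#' Marker-positive fraction of the tumor-cell area
#'
#' Tumor pixels whose classification confidence (tissue-class posterior)
#' reaches `confidence_threshold` form the eligible tumor area; the fraction
#' of that area with marker intensity at or above `positivity_threshold` is
#' the positive-area percentage (e.g. the PDGFRB-positive tumor fraction).
#'
#' @param image a [multiplex_image()]
#' @param compartments a `compartment_map`
#' @param marker_channel channel name (e.g. `"PDGFRB"`)
#' @param positivity_threshold intensity cut in \[0, 1\]; `NULL` = Otsu over
#'   tumor pixels
#' @param confidence_threshold minimum classification confidence, default
#'   0.85
#' @return a `positivity_result`: patient_id, positive_area and
#'   total_tumor_area (pixel counts), ratio_percent (`NA` when no eligible
#'   tumor), thresholds used
#' @export
classify_tumor_positivity <- function(image, compartments, marker_channel,
                                      positivity_threshold = NULL,
                                      confidence_threshold = 0.85) {
  stopifnot(inherits(image, "multiplex_image"),
            inherits(compartments, "compartment_map"),
            marker_channel %in% names(image$channels),
            confidence_threshold >= 0, confidence_threshold <= 1)
  ch <- image$channels[[marker_channel]]
  invalid <- image$invalid %||% matrix(FALSE, nrow(ch), ncol(ch))
  tumor <- compartments$labels == 1L & !invalid
  eligible <- tumor & compartments$tumor_posterior >= confidence_threshold
  if (is.null(positivity_threshold)) {
    if (!any(tumor)) stop("no tumor pixels to derive a threshold from",
                          call. = FALSE)
    positivity_threshold <- otsu_threshold(ch[tumor])
  }
  stopifnot(positivity_threshold >= 0, positivity_threshold <= 1)
  positive <- eligible & (ch >= positivity_threshold)
  n_el <- sum(eligible); n_pos <- sum(positive)
  structure(list(patient_id = image$patient_id,
                 core_id = image$core_id,
                 positive_area = n_pos, total_tumor_area = n_el,
                 ratio_percent = if (n_el > 0) 100 * n_pos / n_el else
                   NA_real_,
                 positivity_threshold = positivity_threshold,
                 confidence_threshold = confidence_threshold),
            class = "positivity_result")
}

#' Pool per-core positivity into per-patient fractions
#'
#' Areas are summed across a patient's cores before forming the ratio
#' (area-weighted pooled fraction).
#'
#' @param results list of `positivity_result`s
#' @return data.frame: patient_id, positive_area, total_tumor_area,
#'   ratio_percent
#' @export
aggregate_positivity <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(patient_id = r$patient_id, positive_area = r$positive_area,
               total_tumor_area = r$total_tumor_area,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(df[c("positive_area", "total_tumor_area")],
                          by = df["patient_id"], FUN = sum)
  agg$ratio_percent <- ifelse(agg$total_tumor_area > 0,
                              100 * agg$positive_area / agg$total_tumor_area,
                              NA_real_)
  agg
}
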