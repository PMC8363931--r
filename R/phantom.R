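#' Multi-channel core image container
#'
#' A per-core stack of co-registered channel images with physical pixel size.
#' Channels are matrices of intensities in \[0, 1\] (16-bit quantized for
#' rendered phantoms); `invalid` marks pixels without valid signal (e.g.
#' out-of-frame after registration), which are excluded from every mask and
#' mean downstream.
#'
#' @param channels named list of numeric matrices, identical dimensions
#' @param pixel_size_um physical pixel edge length in micrometres (> 0)
#' @param core_id,patient_id identifiers
#' @param round_id named character vector: staining round per channel
#' @param invalid optional logical matrix, `TRUE` = invalid pixel
#' @return an object of class `multiplex_image`
#' @export
multiplex_image <- function(channels, pixel_size_um, core_id = "core",
                            patient_id = NA_character_, round_id = NULL,
                            invalid = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must have identical dimensions", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            pixel_size_um > 0)
  for (ch in channels) {
    if (any(!is.finite(ch)) || any(ch < 0)) {
      stop("channel intensities must be finite and >= 0", call. = FALSE)
    }
  }
  if (is.null(round_id)) {
    round_id <- stats::setNames(rep("r1", length(channels)), names(channels))
  }
  if (!is.null(invalid)) stop_if_not_same_shape(invalid, channels[[1]])
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 core_id = core_id, patient_id = patient_id,
                 round_id = round_id, invalid = invalid),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_image> core %s (patient %s): %d channel(s), %dx%d px, %.3g um/px\n",
              x$core_id, x$patient_id, length(x$channels), d[1], d[2],
              x$pixel_size_um))
  cat(" channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Disc shape for phantom geometry
#'
#' @param center numeric length-2, (x, y) in micrometres relative to the core
#'   center
#' @param radius_um disc radius in micrometres (>= 0)
#' @export
disc <- function(center, radius_um) {
  stopifnot(length(center) == 2, is.finite(center), radius_um >= 0)
  list(center = as.numeric(center), radius_um = as.numeric(radius_um))
}

#' Per-channel intensity model for phantoms
#'
#' Noise-free intensity at a pixel is
#' `baseline + offsets[compartment] (+ gradient_slope * distance-from-tumor on
#' stroma pixels)`, clamped to \[0, 1\].
#'
#' @param baseline baseline intensity
#' @param offsets named numeric with entries `tumor`, `stroma`, `vessel`,
#'   `autofluorescence`, `background` (missing entries default to 0)
#' @param gradient_slope intensity change per micrometre of distance from the
#'   tumor boundary, applied on stroma pixels only
#' @param round_id staining round label for this channel
#' @export
channel_model <- function(baseline = 0.02, offsets = c(), gradient_slope = 0,
                          round_id = "r1") {
  full <- c(tumor = 0, stroma = 0, vessel = 0, autofluorescence = 0,
            background = 0)
  if (length(offsets)) {
    stopifnot(!is.null(names(offsets)),
              all(names(offsets) %in% names(full)))
    full[names(offsets)] <- offsets
  }
  list(baseline = baseline, offsets = full, gradient_slope = gradient_slope,
       round_id = round_id)
}

#' Specification of a synthetic TMA core phantom
#'
#' Describes a circular 1.0 mm tissue-microarray core containing tumor-cell
#' nests, vessels, autofluorescent debris and stroma, with per-channel
#' compartment-dependent intensities plus Gaussian noise. Pixel centers sit at
#' `(i - 0.5) * pixel_size_um`; a pixel belongs to a shape iff its center is
#' inside, which makes all area oracles unambiguous.
#'
#' @param core_diameter_um core diameter (default 1000, the standard 1.0 mm
#'   TMA core)
#' @param pixel_size_um raster resolution
#' @param tumor_shapes,vessel_shapes,debris_shapes lists of [disc()] shapes;
#'   shapes are clipped to the core disc
#' @param channel_models named list of [channel_model()]s, one per channel
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0)
#' @param seed integer seed; identical specs with identical seeds render
#'   bit-identical images
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(core_diameter_um = 1000, pixel_size_um = 2,
                         tumor_shapes = list(), vessel_shapes = list(),
                         debris_shapes = list(),
                         channel_models = list(marker = channel_model(
                           offsets = c(tumor = 0.1, stroma = 0.3,
                                       vessel = 0.15, autofluorescence = 0.8))),
                         noise_sd = 0.05, seed = 1L) {
  stopifnot(core_diameter_um > 0, pixel_size_um > 0, noise_sd >= 0,
            is.list(channel_models), length(channel_models) >= 1,
            !is.null(names(channel_models)))
  for (s in c(tumor_shapes, vessel_shapes, debris_shapes)) {
    stopifnot(s$radius_um >= 0)
  }
  structure(list(core_diameter_um = core_diameter_um,
                 pixel_size_um = pixel_size_um, tumor_shapes = tumor_shapes,
                 vessel_shapes = vessel_shapes, debris_shapes = debris_shapes,
                 channel_models = channel_models, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# pixel-center coordinate grids in um, origin at core center
pixel_centers <- function(n, pixel_size_um, core_diameter_um) {
  ax <- (seq_len(n) - 0.5) * pixel_size_um - core_diameter_um / 2
  list(x = matrix(ax, n, n, byrow = TRUE), y = matrix(ax, n, n))
}

shapes_mask <- function(shapes, xs, ys) {
  m <- matrix(FALSE, nrow(xs), ncol(xs))
  for (s in shapes) {
    m <- m | ((xs - s$center[1])^2 + (ys - s$center[2])^2 <= s$radius_um^2)
  }
  m
}

#' Render a core phantom with exact ground truth
#'
#' Rasterizes the phantom geometry (pixel-center point-in-disc test), renders
#' each channel as compartment mean + optional stromal gradient + Gaussian
#' noise (clamped to \[0, 1\], 16-bit quantized), and returns the image
#' together with a `ground_truth` object: the four masking-class maps
#' (autofluorescence / vessel / background / tissue), the tumor and stroma
#' compartments, per channel-by-compartment noise-free mean intensities, and
#' (optionally) meso/vessel zone maps computed by brute-force nearest-source
#' search, independent of the production distance-transform code path.
#'
#' Mask priority where shapes overlap: background (outside the core disc),
#' then autofluorescent debris, then vessel, then tumor; remaining tissue is
#' stroma. The four masking classes partition the frame; tumor and stroma
#' partition tissue.
#'
#' @param spec a [phantom_spec()]
#' @param zone_truth compute brute-force zone ground truth? `"auto"` (yes for
#'   rasters up to 200 px across), `TRUE` or `FALSE`
#' @param zones [zone_config()] used for the zone ground truth
#' @return `list(image = multiplex_image, truth = ground_truth)`
#' @export
generate_core_phantom <- function(spec, zone_truth = "auto",
                                  zones = zone_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  px <- spec$pixel_size_um
  n <- as.integer(ceiling(spec$core_diameter_um / px))
  if (n < 8) stop("degenerate raster: core diameter < 8 px", call. = FALSE)

  cc <- pixel_centers(n, px, spec$core_diameter_um)
  core <- (cc$x^2 + cc$y^2) <= (spec$core_diameter_um / 2)^2
  af     <- core & shapes_mask(spec$debris_shapes, cc$x, cc$y)
  vessel <- core & !af & shapes_mask(spec$vessel_shapes, cc$x, cc$y)
  tumor  <- core & !af & !vessel & shapes_mask(spec$tumor_shapes, cc$x, cc$y)
  tissue <- core & !af & !vessel
  stroma <- tissue & !tumor
  background <- !core

  comp <- matrix("background", n, n)
  comp[af] <- "autofluorescence"; comp[vessel] <- "vessel"
  comp[tumor] <- "tumor"; comp[stroma] <- "stroma"

  # distance from the tumor compartment, um, for stromal gradients
  needs_grad <- any(vapply(spec$channel_models,
                           function(m) m$gradient_slope != 0, logical(1)))
  dist_um <- NULL
  if (needs_grad && any(tumor)) {
    dist_um <- EBImage::distmap(matrix(as.numeric(!tumor), n, n)) * px
  }

  comp_levels <- c("tumor", "stroma", "vessel", "autofluorescence",
                   "background")
  set.seed(spec$seed)
  channels <- list(); round_id <- character(0)
  expected <- matrix(NA_real_, length(spec$channel_models),
                     length(comp_levels),
                     dimnames = list(names(spec$channel_models), comp_levels))
  for (nm in names(spec$channel_models)) {
    m <- spec$channel_models[[nm]]
    clean <- matrix(m$baseline, n, n)
    for (k in comp_levels) clean[comp == k] <- m$baseline + m$offsets[[k]]
    if (m$gradient_slope != 0 && !is.null(dist_um)) {
      clean[stroma] <- clean[stroma] + m$gradient_slope * dist_um[stroma]
    }
    clean <- quantize16(clamp01(clean))
    img <- clean
    if (spec$noise_sd > 0) {
      img <- quantize16(clamp01(img + stats::rnorm(n * n, 0, spec$noise_sd)))
    }
    channels[[nm]] <- img
    round_id[nm] <- m$round_id
    for (k in comp_levels) {
      expected[nm, k] <- masked_mean(clean, comp == k)
    }
  }

  image <- multiplex_image(channels, px, core_id = "phantom",
                           round_id = round_id)

  if (identical(zone_truth, "auto")) zone_truth <- n <= 200
  zone_maps <- NULL
  if (isTRUE(zone_truth)) {
    zero_map <- function(kind) {
      new_zone_map(matrix(0L, n, n), kind, zones, px)
    }
    zone_maps <- list(
      meso = if (any(tumor)) {
        compute_zones_brute_force(tumor, stroma, zones, px)
      } else zero_map("meso"),
      vessel = if (any(vessel)) {
        compute_zones_brute_force(vessel, stroma, zones, px, "vessel")
      } else zero_map("vessel"))
  }

  truth <- structure(list(
    masks = list(autofluorescence = af, vessel = vessel,
                 background = background, tissue = tissue),
    compartments = list(tumor = tumor, stroma = stroma),
    core_disc = core,
    expected_mean = expected,
    zone_maps = zone_maps,
    zone_config = zones,
    pixel_size_um = px), class = "ground_truth")
  list(image = image, truth = truth)
}

#' Compartment map from phantom ground truth
#'
#' Bypasses the learned segmentation and builds the compartment labels
#' directly from a phantom's exact masks (confidence 1 everywhere), for
#' oracle-based quantification checks.
#'
#' @param truth a `ground_truth` from [generate_core_phantom()]
#' @return a `compartment_map`
#' @export
compartments_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tumor <- truth$compartments$tumor
  labels <- matrix(0L, nrow(tumor), ncol(tumor))
  labels[tumor] <- 1L
  labels[truth$compartments$stroma] <- 2L
  labels[truth$masks$vessel] <- 3L
  structure(list(labels = labels,
                 tumor_posterior = matrix(as.numeric(tumor), nrow(tumor)),
                 threshold = NA_real_,
                 codes = c(excluded = 0L, tumor = 1L, stroma = 2L,
                           vessel = 3L)),
            class = "compartment_map")
}
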