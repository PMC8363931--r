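#' Concentric stromal distance-zone configuration
#'
#' Stroma is decomposed into concentric rings of width `zone_width_um` at
#' increasing Euclidean distance from a source compartment (the mesothelium,
#' or vessels). Four 12-micrometre zones are the defaults used throughout.
#'
#' @param zone_width_um ring width in micrometres (> 0)
#' @param n_zones number of rings (>= 1)
#' @export
zone_config <- function(zone_width_um = 12, n_zones = 4L) {
  stopifnot(zone_width_um > 0, n_zones >= 1)
  structure(list(zone_width_um = as.numeric(zone_width_um),
                 n_zones = as.integer(n_zones)), class = "zone_config")
}

# Zone label from integer squared pixel distances. Distances are
# center-to-center, so squared distances in px^2 are exact integers; labels
# follow the half-open convention ((k-1)w, kw] -> zone k (ceil). Both the
# distance-transform implementation and the brute-force oracle label through
# this function, so agreement is exact whenever the squared distances agree.
label_from_d2 <- function(d2, pixel_size_um, config) {
  w_px <- config$zone_width_um / pixel_size_um
  lab <- as.integer(ceiling(sqrt(d2) / w_px - 1e-9))
  lab[lab < 0L] <- 0L
  lab[lab > config$n_zones] <- 0L
  lab
}

new_zone_map <- function(labels, source_kind, config, pixel_size_um) {
  structure(list(labels = labels, source_kind = source_kind, config = config,
                 pixel_size_um = pixel_size_um), class = "zone_map")
}

#' Concentric distance zones over stroma
#'
#' Labels every stroma pixel with its distance zone from a source mask:
#' zone k contains stroma pixels whose Euclidean center-to-center distance d
#' (in micrometres) to the nearest source pixel satisfies
#' `(k-1)*w < d <= k*w`; stroma farther than `n_zones * w` keeps label 0 and
#' remains part of the total-stroma aggregates. Distances come from an exact
#' Euclidean distance transform.
#'
#' @param source_mask logical matrix: the source compartment (mesothelium or
#'   vessels); must be disjoint from `stroma_mask`
#' @param stroma_mask logical matrix
#' @param config a [zone_config()]
#' @param pixel_size_um pixel size in micrometres
#' @param source_kind label stored on the result (`"meso"` or `"vessel"`)
#' @return a `zone_map`: integer label matrix (0 = beyond zone n or
#'   non-stroma) plus metadata
#' @export
compute_zones <- function(source_mask, stroma_mask, config = zone_config(),
                          pixel_size_um, source_kind = "meso") {
  stop_if_not_same_shape(source_mask, stroma_mask)
  stopifnot(inherits(config, "zone_config"), pixel_size_um > 0)
  if (any(source_mask & stroma_mask)) {
    stop("source_mask and stroma_mask must be disjoint", call. = FALSE)
  }
  labels <- matrix(0L, nrow(source_mask), ncol(source_mask))
  if (!any(source_mask)) {
    warning("empty source: all zone labels 0", call. = FALSE)
    return(new_zone_map(labels, source_kind, config, pixel_size_um))
  }
  # EBImage::distmap(x) gives each nonzero pixel's exact Euclidean distance
  # to the nearest zero pixel; feed it the complement so zeros = source.
  d <- EBImage::distmap(matrix(as.numeric(!source_mask), nrow(source_mask)))
  d2 <- round(d^2) # exact integer squared distances in px^2
  lab <- label_from_d2(d2, pixel_size_um, config)
  lab[!stroma_mask] <- 0L
  labels[] <- lab
  new_zone_map(labels, source_kind, config, pixel_size_um)
}

#' Brute-force zone oracle
#'
#' Same contract as [compute_zones()], but each stroma pixel's distance is
#' found by direct search over all source pixel centers (chunked to bound
#' memory). Squared distances are exact integers, so labels are exactly
#' comparable with the distance-transform route. Quadratic cost: intended for
#' ground-truth generation and verification on modest rasters.
#'
#' @inheritParams compute_zones
#' @export
compute_zones_brute_force <- function(source_mask, stroma_mask,
                                      config = zone_config(), pixel_size_um,
                                      source_kind = "meso") {
  stop_if_not_same_shape(source_mask, stroma_mask)
  stopifnot(inherits(config, "zone_config"), pixel_size_um > 0)
  if (any(source_mask & stroma_mask)) {
    stop("source_mask and stroma_mask must be disjoint", call. = FALSE)
  }
  labels <- matrix(0L, nrow(source_mask), ncol(source_mask))
  if (!any(source_mask)) {
    warning("empty source: all zone labels 0", call. = FALSE)
    return(new_zone_map(labels, source_kind, config, pixel_size_um))
  }
  src <- which(source_mask, arr.ind = TRUE)
  tgt <- which(stroma_mask, arr.ind = TRUE)
  if (nrow(tgt)) {
    d2min <- numeric(nrow(tgt))
    chunk <- max(1L, as.integer(2e6 / nrow(src)))
    for (start in seq(1L, nrow(tgt), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(tgt))
      D2 <- outer(tgt[idx, 1], src[, 1], "-")^2 +
            outer(tgt[idx, 2], src[, 2], "-")^2
      d2min[idx] <- if (nrow(src) == 1L) D2[, 1] else
        D2[cbind(seq_len(nrow(D2)), max.col(-D2, ties.method = "first"))]
    }
    labels[stroma_mask] <- label_from_d2(d2min, pixel_size_um, config)
  }
  new_zone_map(labels, source_kind, config, pixel_size_um)
}

#' Per-zone mean intensities
#'
#' Mean of a channel over each zone 1..n. Zones with no pixels yield `NA`
#' (missing), never 0.
#'
#' @param channel numeric matrix
#' @param zone_map a `zone_map` from [compute_zones()]
#' @param invalid optional logical matrix of pixels to exclude
#' @return data.frame with columns `zone`, `mean_intensity`, `pixel_count`
#' @export
zone_profile <- function(channel, zone_map, invalid = NULL) {
  stopifnot(inherits(zone_map, "zone_map"))
  stop_if_not_same_shape(channel, zone_map$labels, "channel and zone map")
  lab <- zone_map$labels
  if (!is.null(invalid)) lab[invalid] <- 0L
  zones <- seq_len(zone_map$config$n_zones)
  data.frame(
    zone = zones,
    mean_intensity = vapply(zones, function(k) masked_mean(channel, lab == k),
                            numeric(1)),
    pixel_count = vapply(zones, function(k) sum(lab == k), integer(1)))
}
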