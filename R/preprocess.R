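# translate a matrix by (dy, dx): dest[r, c] = src[r - dy, c - dx];
# uncovered pixels get `fill` and are reported via attr "invalid"
translate_matrix <- function(m, dy, dx, fill = 0) {
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(fill, n_r, n_c)
  invalid <- matrix(TRUE, n_r, n_c)
  rs <- seq_len(n_r); cs <- seq_len(n_c)
  rs_dst <- rs[rs - dy >= 1 & rs - dy <= n_r]
  cs_dst <- cs[cs - dx >= 1 & cs - dx <= n_c]
  if (length(rs_dst) && length(cs_dst)) {
    out[rs_dst, cs_dst] <- m[rs_dst - dy, cs_dst - dx]
    invalid[rs_dst, cs_dst] <- FALSE
  }
  attr(out, "invalid") <- invalid
  out
}

#' Overlay two staining rounds of a TMA core
#'
#' Estimates the rigid integer-pixel displacement of the second staining
#' round relative to the first by exhaustive normalized cross-correlation of
#' a shared reference channel (the nuclear counterstain) over all shifts up
#' to `max_shift_um`, then translates the second round's channels back onto
#' the first and merges both stacks. Round-one pixel values are never
#' altered; pixels of round two that fall out of frame after alignment are
#' flagged invalid and excluded from all downstream masks and means.
#'
#' The returned `shift` is the displacement of round 2 with respect to
#' round 1 in pixels `(dy, dx)`: `round2 ~ translate(round1, shift)`.
#'
#' @param round1,round2 [multiplex_image()]s with equal pixel size
#' @param reference_channel channel name present in both rounds
#' @param max_shift_um search radius in micrometres
#' @return `list(shift = c(dy, dx), shift_um = c(dy, dx) * px, fused =
#'   multiplex_image)`; round-2 channels that collide with round-1 names get
#'   a `.2` suffix
#' @export
register_rounds <- function(round1, round2, reference_channel = "DAPI",
                            max_shift_um = 50) {
  stopifnot(inherits(round1, "multiplex_image"),
            inherits(round2, "multiplex_image"))
  if (round1$pixel_size_um != round2$pixel_size_um) {
    stop("mismatched pixel sizes", call. = FALSE)
  }
  if (!reference_channel %in% names(round1$channels) ||
      !reference_channel %in% names(round2$channels)) {
    stop("reference channel missing from a round", call. = FALSE)
  }
  stop_if_not_same_shape(round1$channels[[1]], round2$channels[[1]],
                         "round images")
  px <- round1$pixel_size_um
  m <- max(1L, as.integer(floor(max_shift_um / px)))
  ref1 <- round1$channels[[reference_channel]]
  ref2 <- round2$channels[[reference_channel]]
  if (stats::sd(ref1) == 0 || stats::sd(ref2) == 0) {
    stop("registration failed: constant reference channel", call. = FALSE)
  }
  n_r <- nrow(ref1); n_c <- ncol(ref1)
  # candidate (dy, dx) = displacement of round 2 relative to round 1:
  # ref2[r + dy, c + dx] should match ref1[r, c] on the overlap
  best <- c(NA_integer_, NA_integer_); best_score <- -Inf
  for (dy in -m:m) {
    r1 <- max(1, 1 - dy):min(n_r, n_r - dy)
    if (!length(r1)) next
    for (dx in -m:m) {
      c1 <- max(1, 1 - dx):min(n_c, n_c - dx)
      if (!length(c1)) next
      a <- ref1[r1, c1, drop = FALSE]
      b <- ref2[r1 + dy, c1 + dx, drop = FALSE]
      if (length(a) < 9) next
      s <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
      if (is.finite(s) && s > best_score) {
        best_score <- s; best <- c(dy, dx)
      }
    }
  }
  if (!is.finite(best_score)) {
    stop("registration failed: correlation undefined", call. = FALSE)
  }
  if (any(abs(best) >= m)) {
    stop("registration failed: estimated shift hits the search boundary",
         call. = FALSE)
  }
  # align round 2 onto round 1 by undoing the displacement
  channels <- round1$channels
  round_id <- round1$round_id
  invalid <- if (is.null(round1$invalid)) {
    matrix(FALSE, n_r, n_c)
  } else round1$invalid
  for (nm in names(round2$channels)) {
    shifted <- translate_matrix(round2$channels[[nm]], -best[1], -best[2])
    invalid <- invalid | attr(shifted, "invalid")
    out_nm <- if (nm %in% names(channels)) paste0(nm, ".2") else nm
    attr(shifted, "invalid") <- NULL
    channels[[out_nm]] <- shifted
    round_id[out_nm] <- round2$round_id[[nm]]
  }
  fused <- multiplex_image(channels, px, core_id = round1$core_id,
                           patient_id = round1$patient_id,
                           round_id = round_id, invalid = invalid)
  list(shift = best, shift_um = best * px, score = best_score, fused = fused)
}

#' Quality control of a TMA core ("spot")
#'
#' A core passes QC when the fraction of the core disc covered by tissue
#' reaches `min_tissue_fraction` (inclusive bound) and registration of its
#' staining rounds succeeded. Failing cores are excluded whole from
#' quantification.
#'
#' @param image a [multiplex_image()]
#' @param tissue_mask logical matrix of tissue pixels
#' @param min_tissue_fraction minimum tissue fraction of the core disc
#' @param registration_ok did round registration succeed?
#' @param shift_um registration shift `(dy, dx)` in micrometres
#' @return a `qc_report`: core_id, tissue_fraction, registration_shift_um,
#'   passed, reasons
#' @export
qc_core <- function(image, tissue_mask, min_tissue_fraction = 0.1,
                    registration_ok = TRUE, shift_um = c(0, 0)) {
  stopifnot(inherits(image, "multiplex_image"))
  stop_if_not_same_shape(tissue_mask, image$channels[[1]], "tissue mask")
  n_r <- nrow(tissue_mask); n_c <- ncol(tissue_mask)
  # inscribed core disc in pixel-center coordinates
  r_px <- min(n_r, n_c) / 2
  yc <- matrix(seq_len(n_r) - 0.5 - n_r / 2, n_r, n_c)
  xc <- matrix(seq_len(n_c) - 0.5 - n_c / 2, n_r, n_c, byrow = TRUE)
  disc_px <- sum(xc^2 + yc^2 <= r_px^2)
  frac <- sum(tissue_mask) / disc_px
  reasons <- character(0)
  if (frac < min_tissue_fraction) reasons <- c(reasons, "insufficient tissue")
  if (!registration_ok) reasons <- c(reasons, "registration failed")
  structure(list(core_id = image$core_id, tissue_fraction = frac,
                 registration_shift_um = shift_um,
                 passed = length(reasons) == 0, reasons = reasons),
            class = "qc_report")
}
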