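#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Quantize intensities to the 16-bit grid
#'
#' Intensities are stored at 16-bit depth (values k/65535, k integer), the
#' depth fluorescence scanners commonly export. Quantizing at image-creation
#' time makes TIFF round trips bit-exact.
#'
#' @param x numeric vector/matrix in \[0, 1\]
#' @return x snapped to the nearest multiple of 1/65535
#' @keywords internal
quantize16 <- function(x) round(x * 65535) / 65535

# FNV-1a 32-bit hash of a character string; used for config hashes and for
# deriving per-stage seeds from the single run seed. Returns a double holding
# an integer in [0, 2^32); arithmetic kept exact by 16-bit split products.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 2^32
  }
  h
}

fnv1a_hex <- function(s) {
  h <- fnv1a(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a per-stage seed from the run seed
#'
#' Stages of a pipeline run draw their randomness from seeds derived from the
#' single run seed by hashing the stage name, so each stage is independently
#' reproducible.
#'
#' @param seed integer run seed
#' @param stage character stage name
#' @return integer seed in \[0, 2^31)
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  as.integer((abs(seed) + fnv1a(stage)) %% (2^31 - 1))
}

# mean returning NA (never 0) on an empty mask -- the package-wide
# missing-data convention for intensity summaries
masked_mean <- function(channel, mask) {
  if (!any(mask)) return(NA_real_)
  mean(channel[mask])
}

stop_if_not_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
  }
}
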