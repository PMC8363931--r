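# Shared fixture builders. All fixtures are generated in code; sizes are kept
# small so each file's tests run in seconds.

# single centered tumor disc inside a small core, one or more channels
annulus_phantom <- function(tumor_radius_um = 120, core_diameter_um = 400,
                            pixel_size_um = 2, noise_sd = 0,
                            channel_models = NULL, seed = 1,
                            vessel_shapes = list(), debris_shapes = list(),
                            zone_truth = "auto") {
  if (is.null(channel_models)) {
    channel_models <- list(marker = channel_model(
      0.02, c(tumor = 0.25, stroma = 0.12, vessel = 0.1,
              autofluorescence = 0.7)))
  }
  generate_core_phantom(
    phantom_spec(core_diameter_um, pixel_size_um,
                 tumor_shapes = list(disc(c(0, 0), tumor_radius_um)),
                 vessel_shapes = vessel_shapes,
                 debris_shapes = debris_shapes,
                 channel_models = channel_models,
                 noise_sd = noise_sd, seed = seed),
    zone_truth = zone_truth)
}

# multi-channel phantom with distinct compartment signatures, suitable for
# training/evaluating the masking classifier
classifier_phantom <- function(seed = 1, noise_sd = 0.03,
                               core_diameter_um = 320, pixel_size_um = 4) {
  mods <- list(
    DAPI = channel_model(0.02, c(tumor = 0.5, stroma = 0.35, vessel = 0.3,
                                 autofluorescence = 0.7)),
    CK5 = channel_model(0.02, c(tumor = 0.55, stroma = 0.05, vessel = 0.05,
                                autofluorescence = 0.6)),
    FAP = channel_model(0.02, c(tumor = 0.08, stroma = 0.3, vessel = 0.1,
                                autofluorescence = 0.7)))
  R <- core_diameter_um / 2
  generate_core_phantom(
    phantom_spec(core_diameter_um, pixel_size_um,
                 tumor_shapes = list(disc(c(-0.2 * R, 0), 0.45 * R),
                                     disc(c(0.4 * R, 0.3 * R), 0.3 * R)),
                 vessel_shapes = list(disc(c(0.1 * R, -0.55 * R), 24),
                                      disc(c(-0.5 * R, 0.5 * R), 18)),
                 debris_shapes = list(disc(c(0.6 * R, -0.2 * R), 16)),
                 channel_models = mods, noise_sd = noise_sd, seed = seed),
    zone_truth = FALSE)
}

truth_class_labels <- function(truth) {
  lab <- matrix("background", nrow(truth$masks$tissue),
                ncol(truth$masks$tissue))
  lab[truth$masks$autofluorescence] <- "autofluorescence"
  lab[truth$masks$vessel] <- "vessel"
  lab[truth$masks$tissue] <- "tissue"
  lab
}

# deterministic smooth random texture (for registration tests)
smooth_texture <- function(n, seed = 1, sigma = 3) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m <- EBImage::gblur(m, sigma)
  (m - min(m)) / (max(m) - min(m))
}

# tiny survival data without ties for likelihood-oracle checks
tiny_surv <- function(n = 7, seed = 1) {
  set.seed(seed)
  data.frame(months = sort(stats::rexp(n, 0.1) + seq_len(n) * 1e-3),
             event = rep(1L, n), x = round(stats::rnorm(n), 2))
}

# hand-coded Cox negative log partial likelihood (Breslow = Efron when no
# ties), the brute-force oracle for cox_fit on tie-free data
cox_nll_oracle <- function(beta, months, event, x) {
  ord <- order(months)
  months <- months[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  nll <- 0
  for (i in seq_along(months)) {
    if (event[i] == 1) {
      risk <- which(months >= months[i]) # no ties: unique event times
      nll <- nll - (eta[i] - log(sum(exp(eta[risk]))))
    }
  }
  nll
}
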