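test_that("mean intensity follows the masked-mean conventions", {
  ch <- matrix(0.3, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  expect_equal(mean_intensity(ch, mask), 0.3)
  half <- ch; half[1:5, 1:5] <- 0; half[1:5, 6:10] <- 1
  expect_equal(mean_intensity(half, mask), 0.5)
  expect_true(is.na(mean_intensity(ch, matrix(FALSE, 10, 10))))
  # affine equivariance on a fixed mask
  set.seed(1)
  r <- matrix(runif(100), 10, 10)
  expect_equal(mean_intensity(0.5 * r + 0.2, mask),
               0.5 * mean_intensity(r, mask) + 0.2)
  # invalid pixels are excluded
  inv <- matrix(FALSE, 10, 10); inv[1, ] <- TRUE
  expect_equal(mean_intensity(half, mask, invalid = inv),
               mean(half[2:5, ]))
})

core_measurements <- function(patient, core, values) {
  data.frame(patient_id = patient, core_id = core,
             marker = names(values), compartment = "meso",
             mean_intensity = unname(values), pixel_count = 100L,
             stringsAsFactors = FALSE)
}

test_that("patient tables average across QC-passed cores", {
  m <- rbind(core_measurements("P1", "c1", c(FAP = 0.2)),
             core_measurements("P1", "c2", c(FAP = 0.4)),
             core_measurements("P2", "c3", c(FAP = 0.7)))
  tab <- build_patient_table(m)
  expect_equal(tab$FAP_meso[tab$patient_id == "P1"], 0.3)
  expect_equal(tab$FAP_meso[tab$patient_id == "P2"], 0.7)
  expect_identical(attr(tab, "scale"), "raw")
  expect_equal(unname(attr(tab, "n_cores")["P1", "FAP_meso"]), 2L)

  # permutation invariance in core order
  tab_rev <- build_patient_table(m[rev(seq_len(nrow(m))), ])
  expect_equal(tab_rev[order(tab_rev$patient_id), ],
               tab[order(tab$patient_id), ], ignore_attr = TRUE)

  # QC-failed cores drop out; patients with no passed core are excluded
  expect_message(tab_qc <- build_patient_table(m, passed_cores = c("c1")),
                 "no QC-passed core")
  expect_equal(tab_qc$FAP_meso, 0.2)

  expect_error(build_patient_table(rbind(m, m[1, ])), "duplicate")
})

test_that("phantom measurements match ground-truth expected means", {
  # compartment means sit well inside [0, 1] so additive noise is never
  # clamped and the sample mean stays unbiased
  mods <- list(FAP = channel_model(0.02, c(tumor = 0.3, stroma = 0.45,
                                           vessel = 0.3,
                                           autofluorescence = 0.7)),
               SPARC = channel_model(0.02, c(tumor = 0.35, stroma = 0.25)))
  sd_noise <- 0.05
  ph <- annulus_phantom(channel_models = mods, noise_sd = sd_noise,
                        seed = 21, zone_truth = FALSE)
  ph$image$patient_id <- "P1"
  cp <- compartments_from_truth(ph$truth)
  zm <- compute_zones(cp$labels == 1L, cp$labels == 2L, zone_config(), 2)
  zv <- suppressWarnings(compute_zones(cp$labels == 3L, cp$labels == 2L,
                                       zone_config(), 2, "vessel"))
  meas <- measure_core(ph$image, cp, zm, zv, c("FAP", "SPARC"))
  tab <- build_patient_table(meas)
  for (mk in c("FAP", "SPARC")) {
    for (comp in c("meso", "stroma")) {
      truth_name <- c(meso = "tumor", stroma = "stroma")[[comp]]
      expected <- ph$truth$expected_mean[mk, truth_name]
      n_px <- meas$pixel_count[meas$marker == mk &
                                 meas$compartment == comp]
      se <- sd_noise / sqrt(n_px)
      expect_lt(abs(tab[[paste0(mk, "_", comp)]] - expected), 3 * se)
    }
  }
})

test_that("the x1000 Cox scale is applied once and tracked", {
  tab <- data.frame(patient_id = c("P1", "P2"),
                    FAP_meso = c(0.0123, 0))
  attr(tab, "scale") <- "raw"
  sc <- scale_for_cox(tab)
  expect_equal(sc$FAP_meso, c(12.3, 0))
  expect_identical(attr(sc, "scale"), "x1000")
  expect_error(scale_for_cox(sc), "already")
})

test_that("scaling by 1000 divides the Cox coefficient, not the science", {
  co <- generate_cohort(cohort_spec(800, beta = log(1.02), seed = 31))
  co$xs <- co$marker * 1000
  b_raw <- cox_fit(co, "marker")$beta
  b_scaled <- cox_fit(co, "xs")$beta
  expect_equal(b_scaled, b_raw / 1000, tolerance = 1e-8)
})

test_that("positive-area fractions follow the area oracle and thresholds", {
  # marker-high sub-disc of radius 60 inside a tumor disc of radius 120
  mods <- list(PDGFRB = channel_model(0, c(tumor = 0.1)),
               CK5 = channel_model(0.02, c(tumor = 0.6)))
  ph <- annulus_phantom(channel_models = mods, noise_sd = 0, seed = 2,
                        zone_truth = FALSE)
  n <- nrow(ph$image$channels$PDGFRB)
  cc <- (matrix(seq_len(n), n, n, byrow = TRUE) - 0.5) * 2 - 200
  rr <- (matrix(seq_len(n), n, n) - 0.5) * 2 - 200
  sub <- (cc^2 + rr^2) <= 60^2
  ph$image$channels$PDGFRB[sub] <- 0.9
  cp <- compartments_from_truth(ph$truth)
  res <- classify_tumor_positivity(ph$image, cp, "PDGFRB",
                                   positivity_threshold = 0.5)
  expect_lt(abs(res$ratio_percent - 100 * (60 / 120)^2) /
              (100 * (60 / 120)^2), 0.03)
  expect_lte(res$positive_area, res$total_tumor_area)

  # saturated / silent markers give 100% / 0%
  hi <- ph; hi$image$channels$PDGFRB[cp$labels == 1L] <- 0.9
  expect_equal(classify_tumor_positivity(hi$image, cp, "PDGFRB",
                                         0.5)$ratio_percent, 100)
  lo <- ph; lo$image$channels$PDGFRB[] <- 0
  expect_equal(classify_tumor_positivity(lo$image, cp, "PDGFRB",
                                         0.5)$ratio_percent, 0)

  # monotone non-increasing in the positivity threshold
  set.seed(5)
  noisy <- ph
  noisy$image$channels$PDGFRB <- matrix(runif(n * n), n, n)
  ratios <- vapply(seq(0.1, 0.9, 0.1), function(thr) {
    classify_tumor_positivity(noisy$image, cp, "PDGFRB",
                              thr)$ratio_percent
  }, numeric(1))
  expect_true(all(diff(ratios) <= 0))

  # confidence filter: no eligible tumor -> missing ratio
  low_conf <- cp
  low_conf$tumor_posterior[] <- 0.5
  res_nc <- classify_tumor_positivity(ph$image, low_conf, "PDGFRB", 0.5,
                                      confidence_threshold = 0.85)
  expect_true(is.na(res_nc$ratio_percent))
  expect_equal(res_nc$total_tumor_area, 0)
})

test_that("per-patient positivity pools areas before forming the ratio", {
  r1 <- structure(list(patient_id = "P1", core_id = "c1", positive_area = 10,
                       total_tumor_area = 100), class = "positivity_result")
  r2 <- structure(list(patient_id = "P1", core_id = "c2", positive_area = 90,
                       total_tumor_area = 300), class = "positivity_result")
  agg <- aggregate_positivity(list(r1, r2))
  expect_equal(agg$ratio_percent, 100 * 100 / 400) # area-weighted, not 21.7
})
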