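test_that("a separable two-class toy problem trains to perfect accuracy", {
  set.seed(1)
  f <- rbind(cbind(rnorm(100, 0, 0.1), rnorm(100, 0, 0.1)),
             cbind(rnorm(100, 1, 0.1), rnorm(100, 1, 0.1)))
  colnames(f) <- c("a.raw", "b.raw")
  lab <- rep(c("lo", "hi"), each = 100)
  cl <- train_pixel_classifier(f, lab, seed = 1)
  pred <- stats::predict(cl$model, as.data.frame(f),
                         num.threads = 1)$predictions
  expect_equal(colnames(pred)[max.col(pred, "first")], lab)
})

test_that("training refuses label sets with an empty class", {
  f <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a.raw", "b.raw")))
  lab <- factor(rep("x", 10), levels = c("x", "y"))
  expect_error(train_pixel_classifier(f, lab), "missing class")
})

test_that("phantom pixels classify to ground truth on a held-out core", {
  ph_a <- classifier_phantom(seed = 1)
  ph_b <- classifier_phantom(seed = 2)
  tr <- sample_training_pixels(ph_a$image, c(
    ph_a$truth$masks["autofluorescence"], ph_a$truth$masks["vessel"],
    ph_a$truth$masks["background"], list(tissue = ph_a$truth$masks$tissue)),
    n_per_class = 300, seed = 1)
  cl <- train_pixel_classifier(tr$features, tr$labels, seed = 1)
  ms <- classify_pixels(ph_b$image, cl)
  truth_lab <- truth_class_labels(ph_b$truth)
  pred_lab <- matrix("background", nrow(truth_lab), ncol(truth_lab))
  for (nm in names(ms$masks)) pred_lab[ms$masks[[nm]]] <- nm
  expect_gt(mean(pred_lab == truth_lab), 0.95)
  # posteriors sum to one and reproduce the hard masks by argmax
  sums <- apply(ms$posterior, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  cls <- dimnames(ms$posterior)[[3]]
  flat <- matrix(ms$posterior, ncol = length(cls))
  am <- cls[max.col(flat, "first")]
  expect_equal(am, as.vector(pred_lab))
  # hard masks partition the frame
  expect_true(all(Reduce(`+`, ms$masks) == 1))
})

test_that("classification is deterministic for a fixed seed", {
  ph <- classifier_phantom(seed = 3)
  tr <- sample_training_pixels(ph$image, c(
    ph$truth$masks["autofluorescence"], ph$truth$masks["vessel"],
    ph$truth$masks["background"], list(tissue = ph$truth$masks$tissue)),
    n_per_class = 200, seed = 5)
  cl1 <- train_pixel_classifier(tr$features, tr$labels, seed = 7)
  cl2 <- train_pixel_classifier(tr$features, tr$labels, seed = 7)
  expect_identical(classify_pixels(ph$image, cl1)$posterior,
                   classify_pixels(ph$image, cl2)$posterior)
})

test_that("classifier channel set is validated and persists to disk", {
  ph <- classifier_phantom(seed = 4)
  tr <- sample_training_pixels(ph$image, list(
    tissue = ph$truth$masks$tissue, background = ph$truth$masks$background),
    n_per_class = 100, seed = 1)
  cl <- train_pixel_classifier(tr$features, tr$labels, seed = 1)
  wrong <- multiplex_image(list(OTHER = ph$image$channels[[1]]), 4)
  expect_error(classify_pixels(wrong, cl), "channel mismatch")
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(cl, path)
  expect_s3_class(load_classifier(path), "pixel_classifier")
})

truth_mask_set <- function(truth) {
  masks <- c(truth$masks["autofluorescence"], truth$masks["vessel"],
             truth$masks["background"], truth$masks["tissue"])
  post <- array(0, c(nrow(truth$masks$tissue), ncol(truth$masks$tissue), 4),
                dimnames = list(NULL, NULL, names(masks)))
  for (k in seq_along(masks)) post[, , k][masks[[k]]] <- 1
  structure(list(masks = masks, posterior = post), class = "mask_set")
}

test_that("tumor/stroma segmentation follows the tumor-marker signal", {
  ph <- annulus_phantom(channel_models = list(
    DAPI = channel_model(0.02, c(tumor = 0.5, stroma = 0.35)),
    CK5 = channel_model(0.02, c(tumor = 0.6, stroma = 0.05))),
    noise_sd = 0, zone_truth = FALSE)
  ms <- truth_mask_set(ph$truth)
  cp <- segment_components(ph$image, ms, "CK5")
  tissue <- ms$masks$tissue
  # exact compartment conservation
  expect_equal(sum(cp$labels == 1L) + sum(cp$labels == 2L), sum(tissue))
  # tumor area within 3% of the disc oracle (smoothing + morphology slack)
  analytic <- pi * (120 / 2)^2
  expect_lt(abs(sum(cp$labels == 1L) - analytic) / analytic, 0.03)

  # saturated marker: everything tissue is tumor (explicit threshold)
  sat <- ph
  sat$image$channels$CK5 <- matrix(0.9, nrow(tissue), ncol(tissue))
  cp_all <- segment_components(sat$image, ms, "CK5", tumor_threshold = 0.5)
  expect_equal(sum(cp_all$labels == 1L), sum(tissue))
  expect_equal(sum(cp_all$labels == 2L), 0)
  # silent marker: everything tissue is stroma
  sat$image$channels$CK5 <- matrix(0, nrow(tissue), ncol(tissue))
  cp_none <- segment_components(sat$image, ms, "CK5", tumor_threshold = 0.5)
  expect_equal(sum(cp_none$labels == 1L), 0)
  expect_equal(sum(cp_none$labels == 2L), sum(tissue))
})

test_that("raising the tumor threshold never grows the tumor area", {
  ph <- annulus_phantom(channel_models = list(
    CK5 = channel_model(0.02, c(tumor = 0.6, stroma = 0.05))),
    noise_sd = 0.05, zone_truth = FALSE, seed = 6)
  ms <- truth_mask_set(ph$truth)
  areas <- vapply(seq(0.1, 0.7, by = 0.1), function(thr) {
    sum(segment_components(ph$image, ms, "CK5",
                           tumor_threshold = thr)$labels == 1L)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("tumor Dice against ground truth stays high across phantoms", {
  dice <- vapply(1:10, function(seed) {
    ph <- annulus_phantom(channel_models = list(
      CK5 = channel_model(0.02, c(tumor = 0.6, stroma = 0.05))),
      noise_sd = 0.05, zone_truth = FALSE, seed = seed)
    ms <- truth_mask_set(ph$truth)
    cp <- segment_components(ph$image, ms, "CK5")
    pred <- cp$labels == 1L
    truth <- ph$truth$compartments$tumor
    2 * sum(pred & truth) / (sum(pred) + sum(truth))
  }, numeric(1))
  expect_true(all(dice >= 0.9))
})

test_that("segmentation validates inputs", {
  ph <- annulus_phantom(zone_truth = FALSE)
  ms <- truth_mask_set(ph$truth)
  expect_error(segment_components(ph$image, ms, "NOPE"), "not in image")
  empty <- ms
  empty$masks$tissue <- matrix(FALSE, nrow(ms$masks$tissue),
                               ncol(ms$masks$tissue))
  expect_error(segment_components(ph$image, empty, "marker"), "no tissue")
})
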