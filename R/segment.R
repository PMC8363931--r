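MASK_CLASSES <- c("autofluorescence", "vessel", "background", "tissue")

#' Per-pixel feature matrix for pixel classification
#'
#' Features are each channel's raw intensity plus Gaussian-smoothed versions
#' at two scales, the feature family of interactive pixel-classification
#' tools for histology masking.
#'
#' @param image a [multiplex_image()]
#' @param sigmas two smoothing scales in pixels
#' @return numeric matrix, one row per pixel (column-major order), named
#'   columns
#' @export
pixel_features <- function(image, sigmas = c(1, 4)) {
  stopifnot(inherits(image, "multiplex_image"), length(sigmas) == 2)
  cols <- list()
  for (nm in names(image$channels)) {
    ch <- image$channels[[nm]]
    cols[[paste0(nm, ".raw")]] <- as.vector(ch)
    for (s in sigmas) {
      sm <- EBImage::gblur(ch, sigma = s)
      cols[[sprintf("%s.g%g", nm, s)]] <- as.vector(sm)
    }
  }
  do.call(cbind, cols)
}

#' Train the masking pixel classifier
#'
#' A random-forest pixel classifier over intensity + two-scale Gaussian
#' features, returning per-class posterior probabilities. Deterministic for a
#' fixed seed. Intended classes are the four masking classes
#' (autofluorescence, vessel, background, tissue), but any label set with at
#' least one example per declared class is accepted.
#'
#' @param features numeric matrix from [pixel_features()] (rows = labeled
#'   pixels)
#' @param labels factor or character of class labels, one per row
#' @param seed integer seed
#' @param num_trees number of trees
#' @return a `pixel_classifier` (model + feature/channel metadata + format
#'   version)
#' @export
train_pixel_classifier <- function(features, labels, seed = 1L,
                                   num_trees = 100L) {
  labels <- as.factor(labels)
  stopifnot(nrow(features) == length(labels))
  if (any(table(labels) == 0)) {
    stop("missing class in labels: every declared class needs >= 1 example",
         call. = FALSE)
  }
  df <- as.data.frame(features)
  df$.class <- labels
  model <- ranger::ranger(
    dependent.variable.name = ".class", data = df, probability = TRUE,
    num.trees = num_trees, seed = seed, num.threads = 1L)
  channel_names <- unique(sub("\\.(raw|g[0-9.]+)$", "", colnames(features)))
  structure(list(model = model, feature_names = colnames(features),
                 channel_names = channel_names, classes = levels(labels),
                 format_version = 1L), class = "pixel_classifier")
}

#' Sample labeled training pixels from a phantom
#'
#' Draws up to `n_per_class` pixels per masking class using ground-truth
#' masks as labels, giving a supervised training set with known truth.
#'
#' @param image a [multiplex_image()]
#' @param masks named list of logical matrices, one per class
#' @param n_per_class pixels per class
#' @param seed integer seed
#' @param sigmas passed to [pixel_features()]
#' @return list(features, labels)
#' @export
sample_training_pixels <- function(image, masks, n_per_class = 500L,
                                   seed = 1L, sigmas = c(1, 4)) {
  feats <- pixel_features(image, sigmas)
  set.seed(seed)
  idx <- integer(0); lab <- character(0)
  for (nm in names(masks)) {
    w <- which(masks[[nm]])
    if (!length(w)) next
    take <- if (length(w) > n_per_class) sample(w, n_per_class) else w
    idx <- c(idx, take); lab <- c(lab, rep(nm, length(take)))
  }
  list(features = feats[idx, , drop = FALSE], labels = factor(lab))
}

#' Classify every pixel of a core into masking classes
#'
#' Applies a trained [train_pixel_classifier()] model, producing per-class
#' posterior maps and hard masks by posterior argmax. The masks are pairwise
#' disjoint and cover the frame; posteriors sum to 1 at every pixel.
#'
#' @param image a [multiplex_image()]
#' @param classifier a `pixel_classifier`
#' @param sigmas smoothing scales; must match training
#' @return a `mask_set`: `masks` (named list of logical matrices) and
#'   `posterior` (pixels-by-classes matrix stored as an array
#'   rows x cols x classes)
#' @export
classify_pixels <- function(image, classifier, sigmas = c(1, 4)) {
  stopifnot(inherits(image, "multiplex_image"),
            inherits(classifier, "pixel_classifier"))
  if (!setequal(names(image$channels), classifier$channel_names)) {
    stop("channel mismatch between image and classifier", call. = FALSE)
  }
  feats <- pixel_features(image, sigmas)
  if (!identical(colnames(feats), classifier$feature_names)) {
    feats <- feats[, classifier$feature_names, drop = FALSE]
  }
  pred <- stats::predict(classifier$model, data = as.data.frame(feats),
                         num.threads = 1L)$predictions
  d <- dim(image$channels[[1]])
  hard <- max.col(pred, ties.method = "first")
  classes <- colnames(pred)
  masks <- lapply(seq_along(classes), function(k) {
    matrix(hard == k, d[1], d[2])
  })
  names(masks) <- classes
  posterior <- array(pred, dim = c(d[1], d[2], length(classes)),
                     dimnames = list(NULL, NULL, classes))
  structure(list(masks = masks, posterior = posterior),
            class = "mask_set")
}

otsu_threshold <- function(values, range = c(0, 1)) {
  img <- EBImage::Image(matrix(values, ncol = 1))
  as.numeric(EBImage::otsu(img, range = range))
}

#' Split tissue into mesothelioma (tumor-cell) and stroma compartments
#'
#' The tumor-marker signal is the pixelwise maximum over the (Gaussian
#' smoothed) tumor-marker channels; tissue pixels at or above
#' `tumor_threshold` (default: Otsu computed over tissue pixels) become
#' tumor after morphological closing-then-opening with a disc element, and
#' the remaining tissue is stroma. Vessel pixels are never part of either
#' compartment.
#'
#' @param image a [multiplex_image()]
#' @param masks a `mask_set` from [classify_pixels()]
#' @param tumor_channels channel names carrying tumor-cell markers (e.g. CK5
#'   or the CK5 + CK5/6 + calretinin combination channel)
#' @param tumor_threshold intensity threshold; `NULL` = Otsu on tissue pixels
#' @param smooth_sigma Gaussian sigma (px) applied to the tumor signal
#' @param morph_radius disc radius (px) of the closing/opening element; 0
#'   disables morphology
#' @return a `compartment_map`: integer `labels` matrix with code table
#'   0 excluded, 1 tumor, 2 stroma, 3 vessel; `tumor_posterior` (tissue-class
#'   posterior on tumor pixels, the confidence map used for
#'   positive-area filtering); `threshold` used
#' @export
segment_components <- function(image, masks, tumor_channels,
                               tumor_threshold = NULL, smooth_sigma = 2,
                               morph_radius = 2) {
  stopifnot(inherits(image, "multiplex_image"), inherits(masks, "mask_set"))
  missing_ch <- setdiff(tumor_channels, names(image$channels))
  if (length(missing_ch)) {
    stop("tumor channels not in image: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  tissue <- masks$masks$tissue
  if (is.null(tissue) || !any(tissue)) stop("no tissue", call. = FALSE)
  vessel <- masks$masks$vessel %||% matrix(FALSE, nrow(tissue), ncol(tissue))

  signal <- NULL
  for (nm in tumor_channels) {
    sm <- if (smooth_sigma > 0) {
      EBImage::gblur(image$channels[[nm]], sigma = smooth_sigma)
    } else image$channels[[nm]]
    signal <- if (is.null(signal)) sm else pmax(signal, sm)
  }
  thr <- tumor_threshold %||% otsu_threshold(signal[tissue])
  raw <- tissue & (signal >= thr)
  if (morph_radius > 0 && any(raw)) {
    kern <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
    cleaned <- EBImage::opening(EBImage::closing(raw * 1, kern), kern) > 0
  } else {
    cleaned <- raw
  }
  tumor <- tissue & cleaned
  stroma <- tissue & !tumor

  labels <- matrix(0L, nrow(tissue), ncol(tissue))
  labels[tumor] <- 1L; labels[stroma] <- 2L; labels[vessel] <- 3L
  tumor_posterior <- matrix(0, nrow(tissue), ncol(tissue))
  if ("tissue" %in% dimnames(masks$posterior)[[3]]) {
    tp <- masks$posterior[, , "tissue"]
    tumor_posterior[tumor] <- tp[tumor]
  } else {
    tumor_posterior[tumor] <- 1
  }
  structure(list(labels = labels, tumor_posterior = tumor_posterior,
                 threshold = thr,
                 codes = c(excluded = 0L, tumor = 1L, stroma = 2L,
                           vessel = 3L)),
            class = "compartment_map")
}

#' Persist / restore a pixel classifier
#'
#' Single-file serialization with an embedded format version.
#' @param classifier a `pixel_classifier`
#' @param path file path
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_classifier") || is.null(obj$format_version)) {
    stop("not a pixel_classifier file", call. = FALSE)
  }
  obj
}
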