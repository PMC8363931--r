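#' Write a core-image fixture bundle to disk
#'
#' Per core: a multi-page TIFF (one 16-bit page per channel). Bundle-level: a
#' channel manifest CSV (`channel_index, marker_name, round_id`), a core
#' index CSV, the clinical CSV (`patient_id, age, sex, side, histology,
#' stage, months, event`, extra columns appended), and optional ground-truth
#' sidecars. Because intensities are 16-bit quantized, a round-trip read
#' reproduces the arrays bit-for-bit.
#'
#' @param path output directory (created if needed)
#' @param images list of [multiplex_image()]s
#' @param truths optional named list of `ground_truth` objects (by core_id)
#' @param cohort optional clinical data.frame
#' @return `path`, invisibly
#' @export
write_fixture_bundle <- function(path, images, truths = NULL,
                                 cohort = NULL) {
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle path: ", path,
                              call. = FALSE)
  stopifnot(length(images) >= 1)
  first <- images[[1]]
  manifest <- data.frame(channel_index = seq_along(first$channels),
                         marker_name = names(first$channels),
                         round_id = unname(first$round_id[
                           names(first$channels)]),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(path, "channels.csv"),
                   row.names = FALSE)
  cores <- do.call(rbind, lapply(images, function(img) {
    data.frame(core_id = img$core_id, patient_id = img$patient_id,
               pixel_size_um = img$pixel_size_um,
               file = paste0(img$core_id, ".tif"), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(cores$core_id)) {
    stop("duplicate core_id in bundle", call. = FALSE)
  }
  utils::write.csv(cores, file.path(path, "cores.csv"), row.names = FALSE)
  for (img in images) {
    if (!identical(names(img$channels), manifest$marker_name)) {
      stop("all cores in a bundle must share the channel layout",
           call. = FALSE)
    }
    tiff::writeTIFF(unname(img$channels),
                    file.path(path, paste0(img$core_id, ".tif")),
                    bits.per.sample = 16L)
    if (!is.null(truths[[img$core_id]])) {
      saveRDS(truths[[img$core_id]],
              file.path(path, paste0(img$core_id, "_truth.rds")))
    }
  }
  if (!is.null(cohort)) {
    lead <- c("patient_id", "age", "sex", "side", "histology", "stage",
              "months", "event")
    cohort <- cohort[c(intersect(lead, names(cohort)),
                       setdiff(names(cohort), lead))]
    utils::write.csv(cohort, file.path(path, "clinical.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param path bundle directory
#' @return list: `images` (named by core_id), `truths` (named list, possibly
#'   empty), `cohort` (or `NULL`)
#' @export
read_fixture_bundle <- function(path) {
  manifest <- utils::read.csv(file.path(path, "channels.csv"),
                              stringsAsFactors = FALSE)
  cores <- utils::read.csv(file.path(path, "cores.csv"),
                           stringsAsFactors = FALSE)
  images <- list(); truths <- list()
  for (i in seq_len(nrow(cores))) {
    pages <- tiff::readTIFF(file.path(path, cores$file[i]), all = TRUE)
    names(pages) <- manifest$marker_name
    images[[cores$core_id[i]]] <- multiplex_image(
      pages, cores$pixel_size_um[i], core_id = cores$core_id[i],
      patient_id = cores$patient_id[i],
      round_id = stats::setNames(manifest$round_id, manifest$marker_name))
    tf <- file.path(path, paste0(cores$core_id[i], "_truth.rds"))
    if (file.exists(tf)) truths[[cores$core_id[i]]] <- readRDS(tf)
  }
  clin <- file.path(path, "clinical.csv")
  cohort <- if (file.exists(clin)) {
    utils::read.csv(clin, stringsAsFactors = FALSE)
  }
  list(images = images, truths = truths, cohort = cohort)
}
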