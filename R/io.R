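# Format plumbing: NIfTI and PNG image/mask pairs (PNG carries a JSON
# spacing sidecar), cohort CSV round-trips.

#' Write an image/mask pair
#'
#' NIfTI (`.nii`/`.nii.gz`) stores the spacing in the header; PNG writes an
#' 8-bit rescaled image, a binary mask, and a `<image>.json` sidecar with
#' the pixel spacing and the intensity window (PNG cannot carry either).
#'
#' @param image numeric matrix.
#' @param mask binary matrix.
#' @param spacing mm per pixel.
#' @param image_path,mask_path output paths; both must share one format.
#' @return invisibly, the image path.
#' @export
write_image_mask_pair <- function(image, mask, spacing,
                                  image_path, mask_path) {
  if (!all(dim(image) == dim(mask))) stop("image/mask shape mismatch")
  if (grepl("\\.nii(\\.gz)?$", image_path)) {
    RNifti::writeNifti(RNifti::asNifti(image, pixdim = c(spacing, spacing)),
                       image_path)
    RNifti::writeNifti(RNifti::asNifti(matrix(as.integer(mask != 0),
                                              nrow(mask), ncol(mask)),
                                       pixdim = c(spacing, spacing)),
                       mask_path)
  } else if (grepl("\\.png$", image_path)) {
    rng <- range(image)
    sc <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    png::writePNG(sc, image_path)
    png::writePNG((mask != 0) * 1, mask_path)
    sidecar <- sub("\\.png$", ".json", image_path)
    jsonlite::write_json(list(pixel_spacing = spacing,
                              intensity_min = rng[1],
                              intensity_max = rng[2]),
                         sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported format (use .nii, .nii.gz or .png): ", image_path)
  }
  invisible(image_path)
}

#' Read an image/mask pair
#'
#' @param image_path,mask_path paths written by [write_image_mask_pair()].
#' @return list with `image` (matrix), `mask` (0/1 integer matrix),
#'   `spacing`.
#' @export
read_image_mask_pair <- function(image_path, mask_path) {
  if (!file.exists(image_path)) stop("missing image file: ", image_path)
  if (!file.exists(mask_path)) stop("missing mask file: ", mask_path)
  if (grepl("\\.nii(\\.gz)?$", image_path)) {
    img <- RNifti::readNifti(image_path)
    spacing <- RNifti::pixdim(img)[1]
    image <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
    mk <- RNifti::readNifti(mask_path)
    mask <- matrix(as.numeric(mk), dim(mk)[1], dim(mk)[2])
  } else if (grepl("\\.png$", image_path)) {
    sidecar <- sub("\\.png$", ".json", image_path)
    if (!file.exists(sidecar)) {
      stop("missing spacing sidecar for PNG pair: ", sidecar)
    }
    meta <- jsonlite::read_json(sidecar)
    spacing <- meta$pixel_spacing
    raw <- png::readPNG(image_path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    image <- raw * (meta$intensity_max - meta$intensity_min) +
      meta$intensity_min
    mask <- png::readPNG(mask_path)
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  } else {
    stop("unsupported format: ", image_path)
  }
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask shapes differ: ", image_path)
  }
  uv <- unique(round(as.numeric(mask), 6))
  if (!all(uv %in% c(0, 1))) {
    stop("mask contains values other than 0/1: ", mask_path)
  }
  list(image = image,
       mask = matrix(as.integer(round(mask) != 0), nrow(mask), ncol(mask)),
       spacing = spacing)
}

#' Write a phantom cohort to disk
#'
#' Paired image/mask files (PNG by default) plus a cohort CSV with one row
#' per phantom: id, the 8 clinical fields, the 3 binary label fields and
#' the decimal category.
#'
#' @param phantoms list of `phantom` objects.
#' @param dir output directory (created if needed).
#' @param format "png" or "nii".
#' @return path of the cohort CSV, invisibly.
#' @export
write_cohort <- function(phantoms, dir, format = c("png", "nii")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") ".png" else ".nii"
  rows <- lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    id <- sprintf("phantom_%04d", i)
    write_image_mask_pair(p$image, p$mask, p$spacing,
                          file.path(dir, paste0(id, "_image", ext)),
                          file.path(dir, paste0(id, "_mask", ext)))
    data.frame(id = id, as.data.frame(p$clinical),
               cell_size = p$label$cell_size,
               keratinization = p$label$keratinization,
               histology = p$label$histology,
               category = p$label$category)
  })
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}

#' Run the full pipeline end to end at a configurable scale
#'
#' simulate -> split -> train the segmentation network -> segment the test
#' split -> extract features (over true masks) -> select biomarkers ->
#' SMOTE-balance -> grid-search a classifier -> evaluate. Every stage seeds
#' its randomness from the single global seed, so a rerun with the same
#' configuration reproduces all artifacts.
#'
#' @param n cohort size.
#' @param image_size phantom side in pixels (divisible by 8).
#' @param seed global seed.
#' @param class_probabilities category distribution for the cohort.
#' @param out_dir optional directory for artifacts (cohort CSV, feature
#'   CSV, metrics JSON); NULL keeps everything in memory.
#' @param train_epochs segmentation training epochs.
#' @param encoder_channels,recurrent_units tiny-model knobs for desk-scale
#'   runs.
#' @param selection_grid feature-count grid.
#' @param classifier_family which classifier to grid-search.
#' @return list with `segmentation` (per-case test reports + mean Dice),
#'   `selection` (a `selection_result`), `evaluation` (an
#'   `evaluation_report`).
#' @export
run_pipeline <- function(n = 60L, image_size = 64L, seed = 1L,
                         class_probabilities = c(0, 0, 0, 0, 0.4, 0, 0.4, 0.2),
                         out_dir = NULL, train_epochs = 10L,
                         encoder_channels = c(8L, 16L, 32L),
                         recurrent_units = 32L,
                         selection_grid = seq(5L, 50L, by = 5L),
                         classifier_family = "random_forest") {
  cfg <- phantom_config(image_size = image_size, pixel_spacing = 1.0,
                        noise_sd = 0.05, seed = seed)
  phantoms <- generate_cohort(cfg, n, class_probabilities)
  sp <- split_cohort(seq_len(n), split_spec(seed = seed + 1L))
  # stage 1: segmentation
  tr <- crfe_train(
    crfe_model_spec(input_size = image_size,
                    encoder_channels = encoder_channels,
                    recurrent_units = recurrent_units,
                    decoder_channels = c(16L, 8L)),
    list(train = phantoms[sp$train], validation = phantoms[sp$validation]),
    train_config(max_epochs = train_epochs, seed = seed + 2L),
    loss_config(pixel_spacing = cfg$pixel_spacing),
    schedule_config())
  seg_reports <- lapply(phantoms[sp$test], function(p) {
    prob <- crfe_predict(tr$model, p$image)[[1]]
    segmentation_report(prob, p$mask, spacing = p$spacing)
  })
  mean_dice <- mean(vapply(seg_reports, `[[`, numeric(1), "dice"))
  # stage 2: radiomics typing
  feats <- extract_cohort(phantoms)
  labels <- vapply(phantoms, function(p) p$label$category, numeric(1))
  tr_idx <- c(sp$train, sp$validation)
  scaler <- standardize_features(feats[tr_idx, , drop = FALSE])
  xtr <- scaler$matrix
  xte <- apply_scaler(scaler, feats[sp$test, , drop = FALSE])
  cfc <- choose_feature_count(xtr, labels[tr_idx],
                              count_grid = selection_grid,
                              seed = seed + 3L)
  sel <- apply_cutoff(cfc$ranking, cutoff = 0.01,
                      max_keep = max(cfc$chosen_count, 30L))
  sm <- smote_balance(xtr[, sel$selected_names, drop = FALSE],
                      labels[tr_idx], seed = seed + 4L)
  fit <- fit_with_grid(sm$matrix, sm$labels,
                       classifier_spec(classifier_family, cv_folds = 5L,
                                       seed = seed + 5L))
  ev <- evaluate(fit, xte[, sel$selected_names, drop = FALSE],
                 labels[sp$test])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(phantoms[seq_len(min(n, 5L))],
                 file.path(out_dir, "phantoms"))
    utils::write.csv(data.frame(id = rownames(feats), feats,
                                check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(mean_test_dice = mean_dice,
           selected_features = sel$selected_names,
           accuracy = ev$accuracy, macro_f1 = ev$macro_f1),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(segmentation = list(reports = seg_reports, mean_dice = mean_dice,
                           log = tr$log),
       selection = sel,
       evaluation = ev)
}
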