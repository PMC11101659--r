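# Dataset container, manifest I/O, augmentation and class balancing.

#' @export
print.lesion_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("lesion_dataset: %d lesions (%d malignant), %d modalities\n",
              nrow(m), sum(m$label == 1L), length(x$samples[[1L]]$images)))
  print(table(split = m$split, label = m$label))
  invisible(x)
}

dataset_subset <- function(dataset, idx) {
  structure(list(samples = dataset$samples[idx],
                 manifest = dataset$manifest[idx, , drop = FALSE],
                 config = dataset$config),
            class = "lesion_dataset")
}

#' Subset a dataset by split
#'
#' @param dataset a `lesion_dataset`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return a `lesion_dataset` restricted to the split.
#' @export
dataset_split <- function(dataset, split) {
  idx <- which(dataset$manifest$split == split)
  if (!length(idx)) stopf("split '%s' is empty", split)
  dataset_subset(dataset, idx)
}

#' Write a lesion dataset to disk
#'
#' Writes one PNG per lesion and modality plus a manifest CSV with columns
#' `lesion_id, split, label, grade, path_bmode, path_doppler, path_elasto`
#' (and mask paths when masks are present) — the same schema the reader
#' expects for real data.
#'
#' @param dataset a `lesion_dataset`.
#' @param dir output directory (created if needed).
#' @param write_params also write a sidecar JSON with the ground-truth
#'   rendering parameters (synthetic data only).
#' @return the manifest path, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir, write_params = FALSE) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  mods <- names(dataset$samples[[1L]]$images)
  for (mod in mods) man[[paste0("path_", mod)]] <- NA_character_
  has_mask <- !is.null(dataset$samples[[1L]]$mask)
  if (has_mask) man$path_mask <- NA_character_
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    for (mod in mods) {
      p <- file.path("images", sprintf("%s_%s.png", s$lesion_id, mod))
      write_image(s$images[[mod]], file.path(dir, p))
      man[[paste0("path_", mod)]][i] <- p
    }
    if (has_mask) {
      p <- file.path("images", sprintf("%s_mask.png", s$lesion_id))
      write_image(array(s$mask + 0, c(dim(s$mask), 3L)), file.path(dir, p))
      man$path_mask[i] <- p
    }
  }
  if (write_params) {
    pars <- lapply(dataset$samples, function(s) {
      p <- attr(s, "params")
      if (is.null(p)) NULL else
        p[c("label", "irregularity", "vessel_count", "stiffness_fraction")]
    })
    names(pars) <- man$lesion_id
    jsonlite::write_json(pars, file.path(dir, "params.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a lesion dataset from a manifest
#'
#' @param manifest_path path to a manifest CSV (paths resolved relative to
#'   its directory).
#' @return a `lesion_dataset`.
#' @export
read_lesion_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(grade = "character"))
  dir <- dirname(manifest_path)
  need <- c("lesion_id", "split", "label", "grade")
  if (!all(need %in% names(man)))
    stopf("manifest lacks required column(s): %s",
          paste(setdiff(need, names(man)), collapse = ", "))
  mods <- sub("^path_", "", grep("^path_(?!mask)", names(man), value = TRUE, perl = TRUE))
  if (!length(mods)) stopf("manifest has no path_<modality> columns")
  if (is.null(man$augmented)) man$augmented <- FALSE
  samples <- lapply(seq_len(nrow(man)), function(i) {
    imgs <- stats::setNames(lapply(mods, function(mod) {
      p <- file.path(dir, man[[paste0("path_", mod)]][i])
      read_image(p)
    }), mods)
    mask <- NULL
    if (!is.null(man$path_mask) && !is.na(man$path_mask[i]))
      mask <- img_gray(read_image(file.path(dir, man$path_mask[i]))) > 0.5
    multimodal_sample(man$lesion_id[i], imgs, man$label[i], man$grade[i], mask)
  })
  structure(list(samples = samples,
                 manifest = man[, c(need, "augmented")],
                 config = NULL),
            class = "lesion_dataset")
}

#' Augmentation policy
#'
#' On-the-fly transform ranges applied jointly to all modalities of a sample
#' during training, plus the offline operations used when oversampling the
#' minority class.
#'
#' @param flip_prob probability of a horizontal flip.
#' @param rotation_range_deg rotation range in degrees.
#' @param brightness_contrast_range multiplicative range for brightness and
#'   contrast.
#' @param crop_fraction_range central-crop fraction range (crop is resized
#'   back to the original dims).
#' @param offline_ops operations available to [balance_classes()].
#' @return object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(flip_prob = 0.5,
                                rotation_range_deg = c(-10, 10),
                                brightness_contrast_range = c(0.9, 1.1),
                                crop_fraction_range = c(0.9, 1.0),
                                offline_ops = c("flip", "rotation", "gaussian_blur")) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            diff(rotation_range_deg) >= 0,
            diff(brightness_contrast_range) >= 0,
            diff(crop_fraction_range) >= 0, crop_fraction_range[2L] <= 1)
  structure(list(flip_prob = flip_prob,
                 rotation_range_deg = rotation_range_deg,
                 brightness_contrast_range = brightness_contrast_range,
                 crop_fraction_range = crop_fraction_range,
                 offline_ops = offline_ops),
            class = "augmentation_policy")
}

#' Randomly augment a multimodal sample
#'
#' Draws one transform (flip / brightness / contrast / crop-resize /
#' rotation) from the policy ranges and applies it identically to all
#' modality images, keeping the paired modalities aligned. Output dimensions
#' always equal input dimensions. A degenerate policy (flip_prob 0, ranges
#' `[1, 1]`, rotation `[0, 0]`) is the identity.
#'
#' @param sample a [multimodal_sample()].
#' @param policy an [augmentation_policy()].
#' @return the augmented sample.
#' @export
augment_sample <- function(sample, policy = augmentation_policy()) {
  do_flip <- stats::runif(1) < policy$flip_prob
  bright <- stats::runif(1, policy$brightness_contrast_range[1L],
                         policy$brightness_contrast_range[2L])
  contrast <- stats::runif(1, policy$brightness_contrast_range[1L],
                           policy$brightness_contrast_range[2L])
  frac <- stats::runif(1, policy$crop_fraction_range[1L],
                       policy$crop_fraction_range[2L])
  angle <- stats::runif(1, policy$rotation_range_deg[1L],
                        policy$rotation_range_deg[2L])
  sample$images <- lapply(sample$images, function(img) {
    if (do_flip) img <- flip_horizontal(img)
    img <- adjust_brightness(img, bright)
    img <- adjust_contrast(img, contrast)
    img <- crop_resize(img, frac)
    if (angle != 0) img <- rotate_image(img, angle)
    img
  })
  sample
}

# One random offline augmentation (flip / rotation / blur) for oversampling.
offline_augment <- function(sample, policy) {
  op <- sample(policy$offline_ops, 1L)
  f <- switch(op,
    flip = flip_horizontal,
    rotation = {
      ang <- stats::runif(1, 2, 10) * sample(c(-1, 1), 1L)
      function(img) rotate_image(img, ang)
    },
    gaussian_blur = {
      sg <- stats::runif(1, 0.6, 1.4)
      function(img) gaussian_blur(img, sg)
    },
    stopf("unknown offline op '%s'", op))
  sample$images <- lapply(sample$images, f)
  sample
}

#' Balance classes by augmented oversampling
#'
#' Oversamples the minority class with randomly transformed copies (flip,
#' rotation or Gaussian blur) until the class counts are equal. Originals
#' are retained; copies are flagged in the manifest (`augmented = TRUE`) and
#' suffixed lesion ids. Augmented copies are excluded from prototype
#' projection candidates.
#'
#' @param dataset a `lesion_dataset`.
#' @param policy an [augmentation_policy()] (supplies `offline_ops`).
#' @param seed optional integer seed.
#' @return the balanced `lesion_dataset`.
#' @export
balance_classes <- function(dataset, policy = augmentation_policy(), seed = NULL) {
  man <- dataset$manifest
  counts <- table(factor(man$label, levels = c(0L, 1L)))
  if (any(counts == 0L)) stopf("cannot balance: one class is empty")
  if (counts[1L] == counts[2L]) return(dataset)
  minority <- as.integer(names(which.min(counts)))
  deficit <- abs(diff(as.integer(counts)))
  with_seed_or_stream(seed, {
    pool <- which(man$label == minority)
    picks <- pool[((seq_len(deficit) - 1L) %% length(pool)) + 1L]
    extra <- vector("list", deficit)
    rows <- vector("list", deficit)
    for (t in seq_len(deficit)) {
      src <- dataset$samples[[picks[t]]]
      cp <- offline_augment(src, policy)
      cp$lesion_id <- sprintf("%s_aug%d", src$lesion_id, t)
      attr(cp, "params") <- attr(src, "params")
      extra[[t]] <- cp
      r <- man[picks[t], , drop = FALSE]
      r$lesion_id <- cp$lesion_id
      r$augmented <- TRUE
      rows[[t]] <- r
    }
    man2 <- rbind(man, do.call(rbind, rows))
    rownames(man2) <- NULL
    structure(list(samples = c(dataset$samples, extra), manifest = man2,
                   config = dataset$config),
              class = "lesion_dataset")
  })
}
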