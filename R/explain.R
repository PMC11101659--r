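# Human-facing explanation: for one query lesion, the representative
# prototype of each (modality, class) cell, its localized matching region in
# the query image, normalised contribution scores, and the overall
# malignancy probability.

#' Select representative prototypes
#'
#' For each modality and each class, picks the prototype of that class with
#' the maximal contribution to its own class logit. Ties are broken by the
#' lowest prototype index. With three modalities and two classes this yields
#' the six displayed prototypes.
#'
#' @param contributions matrix `(M * N) x K`: column `k` holds the
#'   contributions of every prototype to logit `k` (see
#'   [contribution_scores()]).
#' @param bank a [prototype_bank()].
#' @return data.frame with one row per (modality, class): prototype row
#'   index and its own-class contribution.
#' @export
select_representatives <- function(contributions, bank) {
  out <- vector("list", bank$M * bank$K)
  i <- 0L
  for (m in seq_len(bank$M)) {
    rows <- bank_rows(bank, m)
    for (k in seq_len(bank$K)) {
      own <- rows[bank$class_assignment[rows] == k]
      contrib <- contributions[own, k]
      best <- own[which.max(contrib)]          # which.max: lowest index on ties
      i <- i + 1L
      out[[i]] <- data.frame(modality_index = m, class = k - 1L,
                             prototype = best,
                             contribution = contributions[best, k])
    }
  }
  do.call(rbind, out)
}

#' Normalise displayed contribution scores
#'
#' Negative contributions are clipped to zero, and the remainder is scaled
#' to sum to 100. If every selected contribution is non-positive the split
#' is uniform (degenerate rule, stated in the report).
#'
#' @param raw numeric vector of selected contributions.
#' @return percentages summing to 100.
#' @export
normalize_contributions <- function(raw) {
  stopifnot(length(raw) >= 1L)
  cl <- pmax(raw, 0)
  if (sum(cl) <= 0) return(rep(100 / length(raw), length(raw)))
  100 * cl / sum(cl)
}

#' Locate a prototype's matching region in the query image
#'
#' Bilinearly upsamples a per-position activation map to the image size,
#' thresholds at the 95th percentile, and returns the tightest axis-aligned
#' bounding rectangle in 0-based, half-open pixel coordinates
#' `(row0, col0, row1, col1)`.
#'
#' @param activation_map matrix `Hf x Wf` of similarity activations for one
#'   prototype.
#' @param image_dims `c(height, width)` of the query image.
#' @return integer vector `c(row0, col0, row1, col1)`.
#' @export
locate_prototype_region <- function(activation_map, image_dims) {
  if (!all(is.finite(activation_map))) stopf("non-finite activation map")
  up <- resize_image(activation_map, image_dims[1L], image_dims[2L])
  thr <- stats::quantile(up, 0.95, names = FALSE)
  hit <- which(up >= thr, arr.ind = TRUE)
  c(row0 = min(hit[, 1L]) - 1L, col0 = min(hit[, 2L]) - 1L,
    row1 = max(hit[, 1L]), col1 = max(hit[, 2L]))
}

#' Build an explanation report for one lesion
#'
#' Runs the model on a sample and assembles the malignancy probability, the
#' six representative prototypes (with source-lesion provenance), their
#' localized matching regions in the query image and normalised contribution
#' scores, plus policy and model version stamps. Requires a projected model
#' (otherwise the prototypes correspond to no real training patch and the
#' report would not be faithful).
#'
#' @param sample a [multimodal_sample()].
#' @param model a fitted, projected `mupnet`.
#' @return object of class `mupnet_explanation`.
#' @export
build_report <- function(sample, model) {
  if (!all(model$bank$provenance$projected))
    stopf("refusing to explain with an unprojected prototype bank")
  fw <- model_forward(model, sample)
  K <- model$head$K
  contrib <- vapply(seq_len(K), function(k)
    contribution_scores(fw$sim$scores, model$head, k),
    numeric(model$bank$M * model$bank$N))
  reps <- select_representatives(contrib, model$bank)
  reps$modality <- model$modalities[reps$modality_index]
  reps$contribution_pct <- normalize_contributions(reps$contribution)
  prov <- model$bank$provenance[reps$prototype, ]
  reps$source_lesion <- prov$lesion_id
  reps$source_grade <- prov$grade
  regions <- t(vapply(seq_len(nrow(reps)), function(i) {
    m <- reps$modality_index[i]
    j <- reps$prototype[i] - (m - 1L) * model$bank$N
    d <- dim(fw$fmaps[[m]])
    amap <- matrix(fw$sim$activations[[m]][, j], d[1L], d[2L])
    locate_prototype_region(amap, dim(sample$images[[m]])[1:2])
  }, numeric(4L)))
  colnames(regions) <- c("row0", "col0", "row1", "col1")
  structure(list(
    lesion_id = sample$lesion_id,
    malignancy_probability = fw$cls$p_malignant,
    logits = fw$cls$logits,
    representatives = cbind(reps, regions),
    normalization = "percentages over the six displayed prototypes, negative contributions clipped to zero",
    policy = model$policy$allowed_grades,
    schema_version = "1.0",
    model_seed = model$seed
  ), class = "mupnet_explanation")
}

#' @export
print.mupnet_explanation <- function(x, ...) {
  cat(sprintf("Explanation for lesion %s\n", x$lesion_id))
  cat(sprintf("  malignancy probability: %.3f\n", x$malignancy_probability))
  r <- x$representatives
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-8s %-9s prototype %2d from %s (grade %s): %5.1f%%\n",
                r$modality[i], c("benign", "malignant")[r$class[i] + 1L],
                r$prototype[i], r$source_lesion[i], r$source_grade[i],
                r$contribution_pct[i]))
  invisible(x)
}

#' Serialize an explanation report
#'
#' Writes `<lesion_id>_report.json` and a small HTML page; when `dataset` is
#' supplied, also writes query and prototype source thumbnails as PNG.
#'
#' @param report a `mupnet_explanation`.
#' @param dir output directory.
#' @param dataset optional `lesion_dataset` supplying the images.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, dir, dataset = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, sprintf("%s_report.json", report$lesion_id))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  r <- report$representatives
  imgs <- ""
  if (!is.null(dataset)) {
    ids <- dataset$manifest$lesion_id
    qi <- match(report$lesion_id, ids)
    rows <- character(0)
    for (i in seq_len(nrow(r))) {
      si <- match(r$source_lesion[i], ids)
      fn <- sprintf("%s_proto%d.png", report$lesion_id, r$prototype[i])
      if (!is.na(si))
        write_image(dataset$samples[[si]]$images[[r$modality[i]]],
                    file.path(dir, fn))
      rows <- c(rows, sprintf(
        "<tr><td>%s</td><td>%s</td><td><img src='%s' width='96'/></td><td>%.1f%%</td></tr>",
        r$modality[i], c("benign", "malignant")[r$class[i] + 1L], fn,
        r$contribution_pct[i]))
    }
    if (!is.na(qi))
      for (mod in names(dataset$samples[[qi]]$images))
        write_image(dataset$samples[[qi]]$images[[mod]],
                    file.path(dir, sprintf("%s_query_%s.png", report$lesion_id, mod)))
    imgs <- paste(rows, collapse = "\n")
  }
  html <- sprintf(
    "<html><body><h2>Lesion %s</h2><p>Malignancy probability: %.3f</p><p>%s</p><table border='1'>%s</table></body></html>",
    report$lesion_id, report$malignancy_probability, report$normalization, imgs)
  writeLines(html, file.path(dir, sprintf("%s_report.html", report$lesion_id)))
  invisible(json_path)
}
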