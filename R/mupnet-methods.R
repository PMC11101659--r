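# S3 methods for fitted "mupnet" objects.

#' @export
print.mupnet <- function(x, ...) {
  b <- x$bank
  cat("Multimodal prototype network\n")
  cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = ", ")))
  cat(sprintf("  prototypes: %d per modality (%d total), C = %d, top_k = %d\n",
              b$N, b$M * b$N, b$C, x$config$top_k))
  cat(sprintf("  projected: %s\n",
              if (all(b$provenance$projected)) "yes (all prototypes carry provenance)" else "NO"))
  cat(sprintf("  trained: %d epochs (seed %d), final total loss %.4f\n",
              nrow(x$log), x$seed, x$log$total[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.mupnet <- function(object, ...) {
  prov <- object$bank$provenance
  prov$modality <- rep(object$modalities, each = object$bank$N)
  prov$class <- c("benign", "malignant")[object$bank$class_assignment]
  out <- list(model = object, provenance = prov,
              loss = object$log[c(1L, nrow(object$log)), ])
  class(out) <- "summary.mupnet"
  out
}

#' @export
print.summary.mupnet <- function(x, ...) {
  print(x$model)
  cat("\nPrototype provenance:\n")
  print(x$provenance[, c("prototype", "modality", "class", "lesion_id",
                         "grade", "row", "col")])
  cat("\nLoss (first and last epoch):\n")
  print(x$loss, row.names = FALSE)
  invisible(x)
}

#' Head weights of a fitted model
#'
#' @param object a `mupnet`.
#' @param ... unused.
#' @return the `(M * N) x K` classification-head weight matrix, with
#'   modality/prototype row names.
#' @export
coef.mupnet <- function(object, ...) {
  W <- object$head$weights
  rownames(W) <- paste0(rep(object$modalities, each = object$bank$N),
                        "_p", rep(seq_len(object$bank$N), object$bank$M))
  colnames(W) <- c("benign", "malignant")[seq_len(ncol(W))]
  W
}

# Forward pass of one sample through a model: feature maps, similarity and
# classification.
model_forward <- function(model, sample) {
  fmaps <- lapply(seq_along(model$modalities), function(m)
    extractor_forward(sample$images[[m]], model$extractors[[m]])$fmap)
  sim <- similarity_scores(fmaps, model$bank, model$config$epsilon,
                           model$config$top_k)
  cls <- classify(sim$scores, model$head)
  list(fmaps = fmaps, sim = sim, cls = cls)
}

#' Predict malignancy risk for lesions
#'
#' @param object a fitted `mupnet`.
#' @param dataset a `lesion_dataset` (all samples are scored) or a single
#'   [multimodal_sample()].
#' @param type `"prob"` (data frame of probabilities), `"class"` (0/1 at the
#'   configured threshold) or `"scores"` (matrix of similarity scores).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.mupnet <- function(object, dataset, type = c("prob", "class", "scores"),
                           ...) {
  type <- match.arg(type)
  samples <- if (inherits(dataset, "multimodal_sample")) list(dataset)
    else dataset$samples
  S <- matrix(0, length(samples), object$bank$M * object$bank$N)
  p <- numeric(length(samples))
  for (i in seq_along(samples)) {
    fw <- model_forward(object, samples[[i]])
    S[i, ] <- fw$sim$scores
    p[i] <- fw$cls$p_malignant
  }
  ids <- vapply(samples, `[[`, character(1), "lesion_id")
  if (type == "scores") { rownames(S) <- ids; return(S) }
  if (type == "class") return(as.integer(p >= object$config$threshold))
  data.frame(lesion_id = ids, p_malignant = p, stringsAsFactors = FALSE)
}

#' Plot training losses of a fitted model
#'
#' Draws the per-epoch loss components of the training log, with stage-3
#' (last-layer tuning) epochs marked.
#'
#' @param x a `mupnet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mupnet <- function(x, ...) {
  lg <- x$log
  graphics::matplot(lg$epoch, cbind(lg$total, lg$ce), type = "l", lty = 1,
                    col = c("black", "steelblue"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::points(lg$epoch[lg$stage == 3L], lg$total[lg$stage == 3L],
                   pch = 16, cex = 0.6, col = "grey40")
  graphics::legend("topright", c("total", "cross-entropy", "stage 3"),
                   lty = c(1, 1, NA), pch = c(NA, NA, 16),
                   col = c("black", "steelblue", "grey40"), bty = "n")
  invisible(x)
}

#' Verify the projection postcondition of a fitted model
#'
#' Recomputes the latent patch named by each prototype's provenance from the
#' dataset and checks (a) the prototype vector equals that patch exactly at
#' stored precision, and (b) the source lesion's grade is allowed by the
#' candidate policy for the prototype's modality and class.
#'
#' @param model a fitted `mupnet`.
#' @param dataset the dataset the model was trained on.
#' @return TRUE (invisibly) if all checks pass; otherwise an error.
#' @export
check_projection <- function(model, dataset) {
  b <- model$bank
  if (!all(b$provenance$projected)) stopf("bank has unprojected prototypes")
  ids <- dataset$manifest$lesion_id
  for (r in seq_len(nrow(b$provenance))) {
    pr <- b$provenance[r, ]
    m <- ((r - 1L) %/% b$N) + 1L
    i <- match(pr$lesion_id, ids)
    if (is.na(i)) stopf("provenance lesion '%s' not in dataset", pr$lesion_id)
    fmap <- extract_features(dataset$samples[[i]]$images[[m]],
                             model$extractors[[m]])
    patch <- fmap[pr$row, pr$col, ]
    if (!identical(as.numeric(patch), as.numeric(b$vectors[r, ])))
      stopf("prototype %d differs from its source patch", r)
    k <- b$class_assignment[r] - 1L
    ok <- candidate_mask(pr$grade, k, model$modalities[m], k, model$policy)
    if (!ok) stopf("prototype %d source grade '%s' violates the policy", r, pr$grade)
  }
  invisible(TRUE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding extractor parameters, the
#' prototype bank (vectors, class assignment, provenance), head weights and
#' the full configuration, with a schema version stamp.
#'
#' @param model a `mupnet`.
#' @param path file path.
#' @return `write_mupnet` the path invisibly; `read_mupnet` the model.
#' @export
write_mupnet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mupnet
#' @export
read_mupnet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mupnet")) stopf("not a mupnet checkpoint: %s", path)
  if (is.null(model$schema_version)) stopf("checkpoint lacks a schema version")
  model
}
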