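# Core forward computation of the multimodal prototype network: per-modality
# feature extraction, prototype similarity scoring, the structured linear
# head, and per-prototype contribution scores.

DEFAULT_MODALITIES <- c("bmode", "doppler", "elasto")

#' Construct a multimodal sample
#'
#' One lesion: `M` paired images (one per modality), a binary pathology label
#' and an ordinal grade. Images are numeric arrays `H x W x 3` in `[0, 1]`
#' and must share identical height/width.
#'
#' @param lesion_id character identifier.
#' @param images named list of `M` images, names giving the modality order.
#' @param label 0 (benign) or 1 (malignant).
#' @param grade one of `"3"`, `"4a"`, `"4b"`, `"4c"`, `"5"`.
#' @param mask optional binary matrix (lesion mask, shared across modalities).
#' @return object of class `multimodal_sample`.
#' @export
multimodal_sample <- function(lesion_id, images, label, grade, mask = NULL) {
  stopifnot(is.list(images), length(images) >= 1L)
  images <- lapply(images, as_rgb_array)
  dims <- vapply(images, function(x) dim(x)[1:2], integer(2L))
  if (any(dims != dims[, 1L])) stopf("all modality images must share dimensions")
  if (!label %in% c(0L, 1L)) stopf("label must be 0 (benign) or 1 (malignant)")
  grade <- as.character(grade)
  if (!grade %in% GRADE_LEVELS) stopf("unknown grade '%s'", grade)
  structure(list(lesion_id = as.character(lesion_id), images = images,
                 label = as.integer(label), grade = grade, mask = mask),
            class = "multimodal_sample")
}

GRADE_LEVELS <- c("3", "4a", "4b", "4c", "5")

#' Create a prototype bank
#'
#' The learnable prototype set: `N` single-pixel prototypes of `C` channels
#' per modality (`M * N` in total), each allocated to one class. Prototypes
#' are stored as an `(M * N) x C` matrix in modality-major order (row
#' `(m - 1) * N + j` holds prototype `j` of modality `m`), the same order the
#' classification head indexes.
#'
#' @param M number of modalities.
#' @param N prototypes per modality.
#' @param C channels.
#' @param per_class_counts integer vector of length `K` summing to `N`:
#'   prototypes allocated to each class within every modality. Default is an
#'   equal split.
#' @param K number of classes.
#' @param init `"uniform"` draws initial vectors from U(0, 1) (the latent
#'   range of the sigmoid add-on layer); `"zero"` fills with zeros.
#' @return object of class `prototype_bank`.
#' @export
prototype_bank <- function(M = 3L, N = 10L, C = 128L,
                           per_class_counts = NULL, K = 2L,
                           init = c("uniform", "zero")) {
  init <- match.arg(init)
  if (is.null(per_class_counts)) {
    base <- N %/% K
    per_class_counts <- rep(base, K)
    per_class_counts[seq_len(N - base * K)] <- base + 1L
  }
  stopifnot(sum(per_class_counts) == N, length(per_class_counts) == K)
  assignment_one <- rep(seq_len(K), times = per_class_counts)
  vectors <- if (init == "uniform") {
    matrix(stats::runif(M * N * C), M * N, C)
  } else matrix(0, M * N, C)
  structure(list(
    vectors = vectors,
    class_assignment = rep(assignment_one, times = M),
    per_class_counts = as.integer(per_class_counts),
    M = as.integer(M), N = as.integer(N), C = as.integer(C), K = as.integer(K),
    provenance = data.frame(prototype = seq_len(M * N),
                            lesion_id = NA_character_, row = NA_integer_,
                            col = NA_integer_, grade = NA_character_,
                            projected = FALSE)
  ), class = "prototype_bank")
}

# Row indices of the bank belonging to modality m (1-based modality-major).
bank_rows <- function(bank, m) (m - 1L) * bank$N + seq_len(bank$N)

#' Extract latent features from one image
#'
#' Applies a modality's convolutional extractor to one image, producing a
#' `Hf x Wf x C` feature map with `Hf = ceiling(H / downsample)` (likewise
#' for width). Deterministic for fixed parameters and input.
#'
#' @param image `H x W x 3` array (or matrix, treated as grayscale).
#' @param extractor a `feature_extractor` (see [backbone_config()]).
#' @return object of class `feature_map`: the array with attributes
#'   `modality_index`.
#' @export
extract_features <- function(image, extractor) {
  image <- as_rgb_array(image)
  if (dim(image)[3L] != extractor$config$in_channels)
    stopf("extractor expects %d input channels", extractor$config$in_channels)
  fmap <- extractor_forward(image, extractor)$fmap
  structure(fmap, modality_index = extractor$modality_index,
            class = "feature_map")
}

# Squared-distance map between every spatial position of a feature map and
# each of the given prototype rows. Returns npos x nproto matrix; positions
# are column-major over (row, col) of the feature map.
distance_map <- function(fmap, proto) {
  d <- dim(fmap)
  Z <- matrix(fmap, d[1L] * d[2L], d[3L])
  D <- matrix(rowSums(Z^2), nrow(Z), nrow(proto)) +
    matrix(rowSums(proto^2), nrow(Z), nrow(proto), byrow = TRUE) -
    2 * Z %*% t(proto)
  pmax(D, 0)
}

# log-distance activation of the similarity (strictly decreasing in d for
# eps < 1).
sim_activation <- function(d, epsilon) log((d + 1) / (d + epsilon))

#' Prototype similarity scores
#'
#' For every prototype, computes the per-position squared Euclidean distance
#' between the (single-pixel) prototype and each feature-map position, maps
#' distances through `log((d + 1) / (d + epsilon))`, and averages the `top_k`
#' largest activations. `top_k = 1` reduces to max pooling over positions.
#'
#' @param fmaps a single `feature_map` (only if the bank has `M = 1`) or a
#'   list of `M` feature maps, one per modality in bank order.
#' @param bank a [prototype_bank()].
#' @param epsilon small positive stabiliser in the activation denominator.
#' @param top_k pooling parameter; must not exceed the number of feature-map
#'   positions.
#' @return object of class `similarity_result`: list with `scores` (length
#'   `M * N`, modality-major), `distances` and `activations` (lists of
#'   `npos x N` matrices per modality), `epsilon`, `top_k`.
#' @export
similarity_scores <- function(fmaps, bank, epsilon = 1e-4, top_k = 3L) {
  if (!is.list(fmaps) || inherits(fmaps, "feature_map")) fmaps <- list(fmaps)
  if (length(fmaps) != bank$M)
    stopf("need %d feature maps (one per modality), got %d", bank$M, length(fmaps))
  stopifnot(epsilon > 0, is_count(top_k))
  scores <- numeric(bank$M * bank$N)
  distances <- activations <- topk_idx <- vector("list", bank$M)
  for (m in seq_len(bank$M)) {
    fmap <- fmaps[[m]]
    d <- dim(fmap)
    if (d[3L] != bank$C) stopf("feature map channels (%d) != bank C (%d)", d[3L], bank$C)
    npos <- d[1L] * d[2L]
    if (top_k > npos) stopf("top_k (%d) exceeds feature-map positions (%d)", top_k, npos)
    if (!all(is.finite(fmap))) stopf("non-finite feature map (modality %d)", m)
    D <- distance_map(fmap, bank$vectors[bank_rows(bank, m), , drop = FALSE])
    A <- sim_activation(D, epsilon)
    idx <- matrix(0L, top_k, bank$N)
    for (j in seq_len(bank$N)) {
      idx[, j] <- order(A[, j], decreasing = TRUE)[seq_len(top_k)]
      scores[(m - 1L) * bank$N + j] <- mean(A[idx[, j], j])
    }
    distances[[m]] <- D; activations[[m]] <- A; topk_idx[[m]] <- idx
  }
  structure(list(scores = scores, distances = distances,
                 activations = activations, topk_idx = topk_idx,
                 epsilon = epsilon, top_k = as.integer(top_k),
                 fmap_dims = lapply(fmaps, dim)),
            class = "similarity_result")
}

#' Structured classification head
#'
#' The final bias-free linear map from the flattened similarity vector
#' (length `M * N`, modality-major) to `K` class logits.
#'
#' @param weights `(M * N) x K` numeric matrix.
#' @return object of class `classifier_head`.
#' @export
classifier_head <- function(weights) {
  stopifnot(is.matrix(weights), all(is.finite(weights)))
  structure(list(weights = weights, K = ncol(weights)), class = "classifier_head")
}

#' Classify a similarity vector
#'
#' Computes logits `l = t(S) %*% w_h` (no bias) and softmax probabilities.
#' For `K = 2` the probability of class 2 is reported as the malignancy risk.
#'
#' @param S numeric vector of length `M * N`, or a `similarity_result`.
#' @param head a [classifier_head()].
#' @return list with `logits`, `prob` and, for `K = 2`, `p_malignant`.
#' @export
classify <- function(S, head) {
  if (inherits(S, "similarity_result")) S <- S$scores
  if (length(S) != nrow(head$weights))
    stopf("similarity vector length (%d) != head rows (%d)", length(S), nrow(head$weights))
  logits <- as.vector(crossprod(head$weights, S))
  e <- exp(logits - max(logits))
  prob <- e / sum(e)
  out <- list(logits = logits, prob = prob)
  if (head$K == 2L) out$p_malignant <- prob[2L]
  out
}

#' Per-prototype contribution scores
#'
#' The contribution of prototype `(m, j)` to the logit of `target_class` is
#' its similarity score multiplied by the corresponding head weight; the
#' contributions sum exactly to that logit.
#'
#' @param S similarity vector (or `similarity_result`).
#' @param head a [classifier_head()].
#' @param target_class class column index (1-based).
#' @return numeric vector of length `M * N`.
#' @export
contribution_scores <- function(S, head, target_class) {
  if (inherits(S, "similarity_result")) S <- S$scores
  if (!target_class %in% seq_len(head$K)) stopf("invalid class index %s", target_class)
  as.vector(S * head$weights[, target_class])
}
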