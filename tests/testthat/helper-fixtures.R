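# Shared fixtures, all generated in code.

# A deterministic bank with chosen prototype vectors.
make_bank <- function(M = 1L, N = 2L, C = 3L, vectors = NULL,
                      per_class_counts = NULL) {
  bank <- prototype_bank(M = M, N = N, C = C,
                         per_class_counts = per_class_counts, init = "zero")
  if (!is.null(vectors)) bank$vectors <- vectors
  bank
}

fmap1 <- function(values, h, w, C, modality_index = 1L) {
  structure(array(values, c(h, w, C)), modality_index = modality_index,
            class = "feature_map")
}

# A small dataset built directly from arrays (fast; no rendering).
array_dataset <- function(labels, grades = NULL, size = 8L, seed = 99L,
                          split = NULL) {
  withr::with_seed(seed, {
    n <- length(labels)
    if (is.null(grades))
      grades <- ifelse(labels == 1L, "5", "3")
    if (is.null(split)) {
      split <- rep("train", n)
    }
    samples <- lapply(seq_len(n), function(i) {
      imgs <- list(bmode = array(runif(size * size * 3), c(size, size, 3)),
                   doppler = array(runif(size * size * 3), c(size, size, 3)),
                   elasto = array(runif(size * size * 3), c(size, size, 3)))
      multimodal_sample(sprintf("A%03d", i), imgs, labels[i], grades[i])
    })
    manifest <- data.frame(
      lesion_id = vapply(samples, `[[`, character(1), "lesion_id"),
      split = split, label = as.integer(labels), grade = grades,
      augmented = FALSE, stringsAsFactors = FALSE)
    structure(list(samples = samples, manifest = manifest, config = NULL),
              class = "lesion_dataset")
  })
}

smoke_config <- function(epochs_total = 16L) {
  mupnet_config(epochs_total = epochs_total, stage1_epochs = 6L,
                stage3_epochs = 2L, batch_size = 16L, n_prototypes = 4L,
                backbone = backbone_config(channels = c(8L, 16L), C = 32L))
}

# One small trained model shared across tests (trained lazily, once).
.smoke_env <- new.env(parent = emptyenv())

get_smoke_fit <- function() {
  if (is.null(.smoke_env$fit)) {
    ds <- simulate_lesions(80, synth_config(image_size = 48L), seed = 2024L)
    model <- mupnet_train(ds, smoke_config(), seed = 7L)
    .smoke_env$fit <- list(model = model, dataset = ds)
  }
  .smoke_env$fit
}

# Independent brute-force similarity oracle: explicit loops over prototypes
# and positions. `fmaps` is a list of per-modality arrays.
brute_similarity_multi <- function(fmaps, bank, epsilon, top_k) {
  scores <- numeric(bank$M * bank$N)
  for (m in seq_len(bank$M)) {
    fmap <- fmaps[[m]]
    d <- dim(fmap)
    for (j in seq_len(bank$N)) {
      p <- bank$vectors[(m - 1L) * bank$N + j, ]
      acts <- c()
      for (cc in seq_len(d[2L])) for (rr in seq_len(d[1L])) {
        dist <- sum((fmap[rr, cc, ] - p)^2)
        acts <- c(acts, log((dist + 1) / (dist + epsilon)))
      }
      scores[(m - 1L) * bank$N + j] <-
        mean(sort(acts, decreasing = TRUE)[seq_len(top_k)])
    }
  }
  scores
}

# Brute-force clustering/separation oracle (triple loop).
brute_min_loss <- function(batch_fmaps, bank, labels, other = FALSE) {
  n <- length(batch_fmaps)
  total <- 0
  for (i in seq_len(n)) {
    k <- labels[i] + 1L
    for (m in seq_len(bank$M)) {
      fmap <- batch_fmaps[[i]][[m]]
      d <- dim(fmap)
      rows <- (m - 1L) * bank$N + seq_len(bank$N)
      keep <- if (other) bank$class_assignment[rows] != k
        else bank$class_assignment[rows] == k
      dmin <- Inf
      for (j in which(keep)) for (cc in seq_len(d[2L])) for (rr in seq_len(d[1L]))
        dmin <- min(dmin, sum((fmap[rr, cc, ] - bank$vectors[rows[j], ])^2))
      total <- total + dmin
    }
  }
  total / n
}

# Synthetic reader-decision table with a known effect of AI assistance.
make_reader_table <- function(n_lesions = 40L, readers = c("R1", "R2"),
                              seed = 5L) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n_lesions)
    rows <- list()
    for (rd in readers) {
      for (phase in c("solo", "ai")) {
        acc <- if (phase == "solo") 0.7 else 0.85
        correct <- runif(n_lesions) < acc
        bm <- ifelse(correct, ifelse(label == 1L, "M", "B"),
                     ifelse(label == 1L, "B", "M"))
        rating <- ifelse(bm == "M", sample(c("4b", "4c", "5"), n_lesions, TRUE),
                         sample(c("3", "4a"), n_lesions, TRUE))
        rows[[paste(rd, phase)]] <- data.frame(
          reader_id = rd, lesion_id = sprintf("L%03d", seq_len(n_lesions)),
          phase = phase, birads_rating = rating, bm_preference = bm,
          label = label, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
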