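# Three-stage training: (1) joint optimisation of the feature extractors and
# prototypes with the classification head frozen, (2) projection of every
# prototype onto its nearest policy-eligible latent training patch, (3)
# last-layer tuning of the head only. The cycle repeats until the epoch
# budget is consumed; a final projection guarantees the returned model's
# prototypes all carry provenance.

#' Training configuration
#'
#' @param epochs_total total number of epochs across all stages.
#' @param lr_initial initial learning rate of the adaptive-moment optimiser.
#' @param lr_decay_every epochs between learning-rate decays.
#' @param lr_decay_factor multiplicative decay every `lr_decay_every`
#'   epochs. The default 0.9 keeps later cycles trainable; 0.1 selects the
#'   literal "decreased by 90% every 5 epochs" reading, which freezes
#'   learning after the first cycle when training a backbone from scratch
#'   (see the methods vignette).
#' @param batch_size minibatch size.
#' @param stage1_epochs,stage3_epochs epochs of joint training and of
#'   last-layer tuning per cycle.
#' @param n_prototypes prototypes per modality (N).
#' @param per_class_counts integer vector summing to `n_prototypes`; default
#'   equal split.
#' @param backbone a [backbone_config()].
#' @param epsilon similarity stabiliser.
#' @param top_k similarity pooling parameter.
#' @param weights a [loss_weights()].
#' @param loss_convention sign convention of the composed objective.
#'   `"canonical"` (default) uses the standard prototype-network form: the
#'   total rewards proximity to own-class prototypes with weight `alpha` and
#'   rewards distance from other-class prototypes with weight `|beta|`.
#'   `"as_published"` composes the printed coefficients literally (alpha on
#'   the negative-valued separation loss, negative beta on the clustering
#'   loss); that form rewards *increasing* both minimum distances, so the
#'   distance terms dominate and representation learning degenerates — it is
#'   retained for comparison, not for use. See the methods vignette.
#' @param l1_mode L1 penalty scope on the head, see [l1_penalty()].
#' @param weight_decay decay factor; `weight_decay_mode = "norm"` applies it
#'   to normalisation-layer parameters only (a no-op for the default
#'   backbone, which has none), `"conv"` applies it conventionally to
#'   convolution weights.
#' @param augmentation an [augmentation_policy()].
#' @param balance oversample the minority class before training.
#' @param threshold decision threshold on the malignancy probability.
#' @return object of class `mupnet_config`.
#' @export
mupnet_config <- function(epochs_total = 80L, lr_initial = 0.001,
                          lr_decay_every = 5L, lr_decay_factor = 0.9,
                          batch_size = 40L,
                          stage1_epochs = 10L, stage3_epochs = 5L,
                          n_prototypes = 10L, per_class_counts = NULL,
                          backbone = backbone_config(),
                          epsilon = 1e-4, top_k = 3L,
                          weights = loss_weights(),
                          loss_convention = c("canonical", "as_published"),
                          l1_mode = c("off_class", "full"),
                          weight_decay = 0.001,
                          weight_decay_mode = c("norm", "conv"),
                          augmentation = augmentation_policy(),
                          balance = TRUE, threshold = 0.5) {
  stopifnot(is_count(epochs_total), is_count(batch_size),
            is_count(stage1_epochs), is_count(stage3_epochs),
            lr_decay_factor > 0, lr_decay_factor <= 1,
            is_count(n_prototypes), is_count(top_k), epsilon > 0)
  structure(list(epochs_total = as.integer(epochs_total),
                 lr_initial = lr_initial,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 stage1_epochs = as.integer(stage1_epochs),
                 stage3_epochs = as.integer(stage3_epochs),
                 n_prototypes = as.integer(n_prototypes),
                 per_class_counts = per_class_counts,
                 backbone = backbone, epsilon = epsilon,
                 top_k = as.integer(top_k), weights = weights,
                 loss_convention = match.arg(loss_convention),
                 l1_mode = match.arg(l1_mode),
                 weight_decay = weight_decay,
                 weight_decay_mode = match.arg(weight_decay_mode),
                 augmentation = augmentation, balance = balance,
                 threshold = threshold),
            class = "mupnet_config")
}

# Coefficients on the positive-valued min-distance terms: total =
# ce + own * min_own + other * min_other + gamma * reg.
loss_coefs <- function(weights, convention) {
  if (convention == "as_published")
    c(own = weights$beta, other = -weights$alpha)
  else
    c(own = weights$alpha, other = weights$beta)
}

#' Learning-rate schedule
#'
#' @param epoch 1-based global epoch.
#' @param config a [mupnet_config()].
#' @return the learning rate for that epoch.
#' @export
lr_at_epoch <- function(epoch, config) {
  config$lr_initial *
    config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
}

#' Structured initialisation of the classification head
#'
#' Entry `(m * N + j, k)` is 1 when prototype `j` of modality `m` is
#' allocated to class `k` and -0.5 otherwise, so each class logit starts as
#' (own-class similarity) - 0.5 * (other-class similarity).
#'
#' @param bank a [prototype_bank()] with complete class assignment.
#' @param K number of classes.
#' @return a [classifier_head()].
#' @export
init_head_weights <- function(bank, K = bank$K) {
  if (anyNA(bank$class_assignment)) stopf("bank has unassigned prototypes")
  W <- matrix(-0.5, bank$M * bank$N, K)
  for (k in seq_len(K)) W[bank$class_assignment == k, k] <- 1
  classifier_head(W)
}

#' Project prototypes onto training patches
#'
#' Replaces every prototype by the nearest (squared L2) latent patch among
#' training samples of its class whose grade the candidate policy allows for
#' that modality, and records the provenance (source lesion and feature-map
#' position). Ties are broken by the lowest (lesion_id, position) in
#' canonical order. The classification head is untouched.
#'
#' @param bank a [prototype_bank()].
#' @param train_features list over samples: each a list of `M` feature maps.
#' @param labels 0/1 vector.
#' @param grades grade strings.
#' @param lesion_ids identifiers, used for provenance and tie-breaking.
#' @param policy a [candidate_policy()].
#' @param modalities modality names, in bank order.
#' @return the projected `prototype_bank`.
#' @export
project_prototypes <- function(bank, train_features, labels, grades,
                               lesion_ids, policy = candidate_policy(),
                               modalities = DEFAULT_MODALITIES) {
  n <- length(train_features)
  stopifnot(length(labels) == n, length(grades) == n, length(lesion_ids) == n)
  ord <- order(lesion_ids)
  for (m in seq_len(bank$M)) {
    rows <- bank_rows(bank, m)
    for (k in seq_len(bank$K)) {
      prot <- rows[bank$class_assignment[rows] == k]
      if (!length(prot)) next
      mask <- candidate_mask(grades, labels, modalities[m], k - 1L, policy)
      if (!any(mask)) {
        ag <- policy$allowed_grades[[modalities[m]]]
        allowed <- if (k == 2L) ag$malignant else ag$benign
        stopf("no prototype candidates for modality '%s', class %d (allowed grades: %s)",
              modalities[m], k - 1L, paste(allowed, collapse = ", "))
      }
      best_d <- rep(Inf, length(prot))
      best <- vector("list", length(prot))
      for (i in ord[mask[ord]]) {
        fmap <- train_features[[i]][[m]]
        D <- distance_map(fmap, bank$vectors[prot, , drop = FALSE])
        dims <- dim(fmap)
        Z <- matrix(fmap, dims[1L] * dims[2L], dims[3L])
        for (q in seq_along(prot)) {
          pos <- which.min(D[, q])           # lowest position on ties
          if (D[pos, q] < best_d[q]) {       # strict <: first lesion wins ties
            best_d[q] <- D[pos, q]
            best[[q]] <- list(vec = Z[pos, ], lesion_id = lesion_ids[i],
                              row = ((pos - 1L) %% dims[1L]) + 1L,
                              col = ((pos - 1L) %/% dims[1L]) + 1L,
                              grade = grades[i])
          }
        }
      }
      for (q in seq_along(prot)) {
        b <- best[[q]]
        bank$vectors[prot[q], ] <- b$vec
        bank$provenance[prot[q], c("lesion_id", "grade")] <- c(b$lesion_id, b$grade)
        bank$provenance$row[prot[q]] <- b$row
        bank$provenance$col[prot[q]] <- b$col
        bank$provenance$projected[prot[q]] <- TRUE
      }
    }
  }
  bank
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function() list(t = 0L)

adam_step <- function(par, grad, st, key, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- st[[paste0(key, ".m")]] %||% 0
  v <- st[[paste0(key, ".v")]] %||% 0
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  st[[paste0(key, ".m")]] <- m
  st[[paste0(key, ".v")]] <- v
  mh <- m / (1 - b1^st$t)
  vh <- v / (1 - b2^st$t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

# ---- forward/backward of the full similarity pathway for one sample --------

zero_like_ext <- function(ext) {
  list(conv = lapply(ext$conv, function(l) list(W = l$W * 0, b = l$b * 0)),
       addon = list(W = ext$addon$W * 0, b = ext$addon$b * 0))
}

add_grads_ext <- function(a, b) {
  for (l in seq_along(a$conv)) {
    a$conv[[l]]$W <- a$conv[[l]]$W + b$conv[[l]]$W
    a$conv[[l]]$b <- a$conv[[l]]$b + b$conv[[l]]$b
  }
  a$addon$W <- a$addon$W + b$addon$W
  a$addon$b <- a$addon$b + b$addon$b
  a
}

# Gradient of the similarity scores w.r.t. one modality's feature-map matrix
# Z (npos x C) and the bank prototypes, given upstream gS (length N for this
# modality). Returns gZ and adds into g_proto rows.
sim_backward_modality <- function(gS, simres, m, bank, Z, g_proto) {
  D <- simres$distances[[m]]
  idx <- simres$topk_idx[[m]]
  k <- simres$top_k
  eps <- simres$epsilon
  gZ <- Z * 0
  rows <- bank_rows(bank, m)
  for (j in seq_len(bank$N)) {
    gj <- gS[j]
    if (gj == 0) next
    pos <- idx[, j]
    dpr <- 1 / (D[pos, j] + 1) - 1 / (D[pos, j] + eps)   # da/dd (negative)
    coef <- (gj / k) * dpr                                # dL/dd at positions
    diffs <- Z[pos, , drop = FALSE] -
      matrix(bank$vectors[rows[j], ], length(pos), bank$C, byrow = TRUE)
    gZ[pos, ] <- gZ[pos, ] + 2 * coef * diffs
    g_proto[rows[j], ] <- g_proto[rows[j], ] - colSums(2 * coef * diffs)
  }
  list(gZ = gZ, g_proto = g_proto)
}

#' Train a multimodal prototype network
#'
#' Fits the full model on the training split of a dataset: balanced classes,
#' on-the-fly augmentation, repeated cycles of joint optimisation,
#' prototype projection and last-layer tuning, with a per-epoch loss log.
#' Fully reproducible given `seed`.
#'
#' @param dataset a `lesion_dataset` whose training split contains both
#'   classes.
#' @param config a [mupnet_config()].
#' @param policy a [candidate_policy()] restricting projection candidates.
#' @param seed integer seed for all randomness (initialisation, shuffling,
#'   augmentation).
#' @param verbose print a line per epoch.
#' @return object of class `mupnet`.
#' @export
mupnet_train <- function(dataset, config = mupnet_config(),
                         policy = candidate_policy(), seed = 1L,
                         verbose = FALSE) {
  man <- dataset$manifest
  if (!all(c(0L, 1L) %in% man$label[man$split == "train"]))
    stopf("training split must contain both classes")
  train <- dataset_split(dataset, "train")
  modalities <- names(train$samples[[1L]]$images)
  M <- length(modalities)
  old_threads <- blas_threads_cpp(1L)
  if (old_threads > 0) on.exit(blas_threads_cpp(old_threads), add = TRUE)

  withr::with_seed(as.integer(seed), {
    if (config$balance) train <- balance_classes(train, config$augmentation)
    extractors <- lapply(seq_len(M), function(m) init_extractor(config$backbone, m))
    bank <- prototype_bank(M = M, N = config$n_prototypes, C = config$backbone$C,
                           per_class_counts = config$per_class_counts,
                           K = 2L, init = "uniform")
    head <- init_head_weights(bank)
    coefs <- loss_coefs(config$weights, config$loss_convention)
    gamma <- config$weights$gamma
    st1 <- adam_new()    # extractors + prototypes
    st3 <- adam_new()    # head
    ntr <- length(train$samples)
    labels <- train$manifest$label
    cyc <- config$stage1_epochs + config$stage3_epochs
    log <- vector("list", config$epochs_total)
    projected_since_stage1 <- TRUE

    project_now <- function() {
      orig <- which(!train$manifest$augmented)
      feats <- lapply(orig, function(i)
        lapply(seq_len(M), function(m)
          extractor_forward(train$samples[[i]]$images[[m]], extractors[[m]])$fmap))
      project_prototypes(bank, feats, labels[orig],
                         train$manifest$grade[orig],
                         train$manifest$lesion_id[orig],
                         policy, modalities)
    }

    for (e in seq_len(config$epochs_total)) {
      pos <- (e - 1L) %% cyc
      stage <- if (pos < config$stage1_epochs) 1L else 3L
      if (stage == 3L && pos == config$stage1_epochs) {
        bank <- project_now()
        projected_since_stage1 <- TRUE
      }
      lr <- lr_at_epoch(e, config)
      perm <- sample.int(ntr)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep <- c(ce = 0, clu = 0, sep = 0, reg = 0, total = 0)
      for (batch in batches) {
        nb <- length(batch)
        fwd <- vector("list", nb)
        fmaps <- vector("list", nb)
        Ss <- matrix(0, nb, M * bank$N)
        sims <- vector("list", nb)
        for (bi in seq_len(nb)) {
          s <- augment_sample(train$samples[[batch[bi]]], config$augmentation)
          fw <- lapply(seq_len(M), function(m)
            extractor_forward(s$images[[m]], extractors[[m]],
                              keep_cache = (stage == 1L)))
          fwd[[bi]] <- fw
          fmaps[[bi]] <- lapply(fw, `[[`, "fmap")
          sims[[bi]] <- similarity_scores(fmaps[[bi]], bank,
                                          config$epsilon, config$top_k)
          Ss[bi, ] <- sims[[bi]]$scores
        }
        ylab <- labels[batch]
        logits <- Ss %*% head$weights
        pm <- exp(logits - apply(logits, 1L, max))
        pm <- pm / rowSums(pm)
        ce <- -mean(log(pmax(pm[cbind(seq_len(nb), ylab + 1L)], 1e-12)))
        mo <- min_own_other(sims, bank, ylab)
        reg <- l1_penalty(head, bank, config$l1_mode)
        tot <- ce + coefs["own"] * mo$own + coefs["other"] * mo$other + gamma * reg
        if (!is.finite(tot))
          stopf("training diverged at epoch %d (non-finite loss: ce=%g own=%g other=%g)",
                e, ce, mo$own, mo$other)
        ep <- ep + nb * c(ce, mo$own, -mo$other, reg, tot)

        glogits <- (pm - stats::model.matrix(~ 0 + factor(ylab, levels = 0:1))) / nb
        if (stage == 1L) {
          g_ext <- lapply(extractors, zero_like_ext)
          g_proto <- bank$vectors * 0
          for (bi in seq_len(nb)) {
            gS_full <- as.vector(head$weights %*% glogits[bi, ])
            for (m in seq_len(M)) {
              d <- dim(fmaps[[bi]][[m]])
              Z <- matrix(fmaps[[bi]][[m]], d[1L] * d[2L], d[3L])
              sb <- sim_backward_modality(gS_full[bank_rows(bank, m)],
                                          sims[[bi]], m, bank, Z, g_proto)
              g_proto <- sb$g_proto
              gZ <- sb$gZ
              # clustering / separation argmin contributions
              am <- mo$argmin[[bi]][[m]]
              for (term in c("own", "other")) {
                a <- am[[term]]
                cf <- coefs[term] / nb
                diff <- Z[a$pos, ] - bank$vectors[a$proto_row, ]
                gZ[a$pos, ] <- gZ[a$pos, ] + 2 * cf * diff
                g_proto[a$proto_row, ] <- g_proto[a$proto_row, ] - 2 * cf * diff
              }
              gb <- extractor_backward(array(gZ, dim = d), fwd[[bi]][[m]],
                                       extractors[[m]])
              g_ext[[m]] <- add_grads_ext(g_ext[[m]], gb)
            }
          }
          if (config$weight_decay_mode == "conv" && config$weight_decay > 0) {
            for (m in seq_len(M)) {
              for (l in seq_along(g_ext[[m]]$conv))
                g_ext[[m]]$conv[[l]]$W <- g_ext[[m]]$conv[[l]]$W +
                  config$weight_decay * extractors[[m]]$conv[[l]]$W
              g_ext[[m]]$addon$W <- g_ext[[m]]$addon$W +
                config$weight_decay * extractors[[m]]$addon$W
            }
          }
          st1$t <- st1$t + 1L
          for (m in seq_len(M)) {
            for (l in seq_along(extractors[[m]]$conv)) {
              up <- adam_step(extractors[[m]]$conv[[l]]$W, g_ext[[m]]$conv[[l]]$W,
                              st1, sprintf("e%dc%dW", m, l), lr)
              extractors[[m]]$conv[[l]]$W <- up$par; st1 <- up$st
              up <- adam_step(extractors[[m]]$conv[[l]]$b, g_ext[[m]]$conv[[l]]$b,
                              st1, sprintf("e%dc%db", m, l), lr)
              extractors[[m]]$conv[[l]]$b <- up$par; st1 <- up$st
            }
            up <- adam_step(extractors[[m]]$addon$W, g_ext[[m]]$addon$W,
                            st1, sprintf("e%daW", m), lr)
            extractors[[m]]$addon$W <- up$par; st1 <- up$st
            up <- adam_step(extractors[[m]]$addon$b, g_ext[[m]]$addon$b,
                            st1, sprintf("e%dab", m), lr)
            extractors[[m]]$addon$b <- up$par; st1 <- up$st
          }
          up <- adam_step(bank$vectors, g_proto, st1, "proto", lr)
          bank$vectors <- up$par; st1 <- up$st
          projected_since_stage1 <- FALSE
        } else {
          gW <- crossprod(Ss, glogits)
          off <- outer(bank$class_assignment, seq_len(head$K), `!=`)
          l1mask <- if (config$l1_mode == "full") off | TRUE else off
          gW <- gW + gamma * sign(head$weights) * l1mask
          st3$t <- st3$t + 1L
          up <- adam_step(head$weights, gW, st3, "head", lr)
          head <- classifier_head(up$par); st3 <- up$st
        }
      }
      ep <- as.numeric(ep / ntr)
      names(ep) <- c("ce", "clu", "sep", "reg", "total")
      log[[e]] <- data.frame(epoch = e, stage = stage, ce = ep[["ce"]],
                             clu = ep[["clu"]], sep = ep[["sep"]],
                             reg = ep[["reg"]], total = ep[["total"]], lr = lr)
      if (verbose)
        message(sprintf("epoch %3d stage %d  ce %.4f clu %.3f sep %.3f total %.4f lr %.2g",
                        e, stage, ep["ce"], ep["clu"], ep["sep"], ep["total"], lr))
    }
    if (!projected_since_stage1 || !all(bank$provenance$projected))
      bank <- project_now()

    structure(list(extractors = extractors, bank = bank, head = head,
                   config = config, policy = policy, modalities = modalities,
                   log = do.call(rbind, log), seed = as.integer(seed),
                   schema_version = "1.0"),
              class = "mupnet")
  })
}

# Own/other minimum distances for a batch, reusing the distance maps cached
# in the similarity results. Returns per-batch means and argmins.
min_own_other <- function(sims, bank, labels) {
  nb <- length(sims)
  own <- other <- 0
  argmin <- vector("list", nb)
  for (bi in seq_len(nb)) {
    k <- labels[bi] + 1L
    am <- vector("list", bank$M)
    for (m in seq_len(bank$M)) {
      rows <- bank_rows(bank, m)
      D <- sims[[bi]]$distances[[m]]
      selo <- bank$class_assignment[rows] == k
      Do <- D[, selo, drop = FALSE]
      w <- arrayInd(which.min(Do), dim(Do))
      own <- own + Do[w[1L], w[2L]]
      amo <- list(pos = w[1L], proto_row = rows[selo][w[2L]])
      Dn <- D[, !selo, drop = FALSE]
      w <- arrayInd(which.min(Dn), dim(Dn))
      other <- other + Dn[w[1L], w[2L]]
      amn <- list(pos = w[1L], proto_row = rows[!selo][w[2L]])
      am[[m]] <- list(own = amo, other = amn)
    }
    argmin[[bi]] <- am
  }
  list(own = own / nb, other = other / nb, argmin = argmin)
}
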