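# Training objective: cross-entropy, clustering loss, separation loss, L1
# regularisation on the head, and their weighted sum.
#
# Sign convention, exactly as the model's published form: the clustering loss
# (min distance to own-class prototypes) is positive-valued and enters the
# total with coefficient beta = -0.08; the separation loss (negative min
# distance to other-class prototypes) is negative-valued and enters with
# alpha = 0.8. `loss_convention = "canonical"` in the training configuration
# selects the usual prototype-network signs instead (see the methods
# vignette for the discussion of this ambiguity).

#' Loss weights
#'
#' @param alpha coefficient on the separation term (default 0.8).
#' @param beta coefficient on the clustering term (default -0.08).
#' @param gamma coefficient on the L1 regularisation term (default 1e-4).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.8, beta = -0.08, gamma = 1e-4) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  structure(list(alpha = alpha, beta = beta, gamma = gamma), class = "loss_weights")
}

# Mean cross-entropy of a list of logit vectors against 0/1 labels.
cross_entropy <- function(logits_list, labels) {
  stopifnot(length(logits_list) == length(labels))
  ce <- vapply(seq_along(labels), function(i) {
    l <- logits_list[[i]]
    m <- max(l)
    (log(sum(exp(l - m))) + m) - l[labels[i] + 1L]
  }, numeric(1))
  mean(ce)
}

# Shared worker for the clustering / separation losses: for each sample and
# modality, the minimum squared distance between any feature-map position and
# any prototype of the reference class set, summed over modalities and
# samples and divided by the batch size. `other = TRUE` uses the non-class
# prototypes. Returns the scalar and, if keep_argmin, the argmin structure
# used for gradients.
min_dist_loss <- function(batch_fmaps, bank, labels, other = FALSE,
                          keep_argmin = FALSE) {
  n <- length(batch_fmaps)
  stopifnot(n == length(labels))
  total <- 0
  argmin <- if (keep_argmin) vector("list", n) else NULL
  for (i in seq_len(n)) {
    k <- labels[i] + 1L
    am_i <- if (keep_argmin) vector("list", bank$M) else NULL
    for (m in seq_len(bank$M)) {
      rows <- bank_rows(bank, m)
      sel <- if (other) bank$class_assignment[rows] != k else
        bank$class_assignment[rows] == k
      if (!any(sel))
        stopf("no %s-class prototype for modality %d, class %d",
              if (other) "other" else "own", m, k)
      D <- distance_map(batch_fmaps[[i]][[m]],
                        bank$vectors[rows[sel], , drop = FALSE])
      w <- arrayInd(which.min(D), dim(D))
      total <- total + D[w[1L], w[2L]]
      if (keep_argmin)
        am_i[[m]] <- list(pos = w[1L], proto_row = rows[sel][w[2L]])
    }
    if (keep_argmin) argmin[[i]] <- am_i
  }
  list(value = total / n, argmin = argmin)
}

#' Clustering loss
#'
#' Encourages at least one feature-map position of each sample to lie close
#' to a prototype of the sample's own class: the per-sample, per-modality
#' minimum squared distance, summed and divided by the batch size. Always
#' non-negative.
#'
#' @param batch_fmaps list over samples; each element a list of `M` feature
#'   maps (arrays `Hf x Wf x C`).
#' @param bank a [prototype_bank()].
#' @param labels integer vector of 0/1 labels.
#' @return scalar loss.
#' @export
clustering_loss <- function(batch_fmaps, bank, labels) {
  min_dist_loss(batch_fmaps, bank, labels, other = FALSE)$value
}

#' Separation loss
#'
#' The negative of the analogous minimum-distance sum taken over the
#' prototypes of the *other* class; always non-positive. Together with its
#' positive coefficient in the total objective it pushes feature patches away
#' from other-class prototypes.
#'
#' @inheritParams clustering_loss
#' @return scalar loss (<= 0).
#' @export
separation_loss <- function(batch_fmaps, bank, labels) {
  -min_dist_loss(batch_fmaps, bank, labels, other = TRUE)$value
}

#' L1 regularisation of the classification head
#'
#' Sum of absolute values of the head weights, restricted by default to the
#' off-class connections (the entries initialised to -0.5), encouraging
#' sparse negative reasoning. `mode = "full"` regularises the whole matrix.
#'
#' @param head a [classifier_head()].
#' @param bank the matching [prototype_bank()] (supplies class assignment).
#' @param mode `"off_class"` or `"full"`.
#' @return scalar (>= 0).
#' @export
l1_penalty <- function(head, bank, mode = c("off_class", "full")) {
  mode <- match.arg(mode)
  if (mode == "full") return(sum(abs(head$weights)))
  off <- outer(bank$class_assignment, seq_len(head$K), `!=`)
  sum(abs(head$weights[off]))
}

#' Total training objective
#'
#' `L = L_ce + alpha * L_sep + beta * L_clu + gamma * L_reg` with the
#' configured weights.
#'
#' @param ce cross-entropy value.
#' @param clu clustering loss value.
#' @param sep separation loss value.
#' @param reg L1 penalty value.
#' @param weights a [loss_weights()].
#' @return object of class `loss_bundle` (list of the components and `total`).
#' @export
total_loss <- function(ce, clu, sep, reg, weights = loss_weights()) {
  stopifnot(is.finite(ce), is.finite(clu), is.finite(sep), is.finite(reg))
  structure(list(ce = ce, clu = clu, sep = sep, reg = reg,
                 total = ce + weights$alpha * sep + weights$beta * clu +
                   weights$gamma * reg,
                 weights = weights),
            class = "loss_bundle")
}

# Gradients of (clustering - style) min-distance terms w.r.t. feature maps
# and prototypes, at the recorded argmins. `coef` multiplies the term in the
# total objective (already including the sign of the loss itself).
# Adds into g_fmaps (same structure as batch_fmaps) and g_proto (MN x C).
accumulate_min_dist_grads <- function(coef, batch_fmaps, bank, argmin,
                                      g_fmaps, g_proto) {
  n <- length(batch_fmaps)
  for (i in seq_len(n)) {
    for (m in seq_len(bank$M)) {
      am <- argmin[[i]][[m]]
      fmap <- batch_fmaps[[i]][[m]]
      d <- dim(fmap)
      Z <- matrix(fmap, d[1L] * d[2L], d[3L])
      diff <- Z[am$pos, ] - bank$vectors[am$proto_row, ]
      g <- (2 * coef / n) * diff
      gz <- matrix(g_fmaps[[i]][[m]], d[1L] * d[2L], d[3L])
      gz[am$pos, ] <- gz[am$pos, ] + g
      g_fmaps[[i]][[m]] <- array(gz, dim = d)
      g_proto[am$proto_row, ] <- g_proto[am$proto_row, ] - g
    }
  }
  list(g_fmaps = g_fmaps, g_proto = g_proto)
}
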