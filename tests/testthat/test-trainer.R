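test_that("head initialisation reproduces the structured 1/-0.5 pattern", {
  # minimal case: one prototype per class
  b <- make_bank(M = 1L, N = 2L, C = 3L)
  expect_equal(init_head_weights(b)$weights,
               matrix(c(1, -0.5, -0.5, 1), 2, 2))

  # arbitrary M, N, per-class split, K
  withr::with_seed(12, {
    for (rep in 1:4) {
      M <- sample(1:4, 1); K <- sample(2:3, 1)
      counts <- sample(1:3, K, replace = TRUE)
      N <- sum(counts)
      b <- prototype_bank(M = M, N = N, C = 2L, per_class_counts = counts,
                          K = K, init = "zero")
      W <- init_head_weights(b)$weights
      expect_true(all(W %in% c(1, -0.5)))
      for (k in seq_len(K)) {
        expect_equal(sum(W[, k] == 1), M * counts[k])
        # column sum per modality follows N_k * 1 + (N - N_k) * (-0.5)
        expect_equal(sum(W[, k]), M * (counts[k] - 0.5 * (N - counts[k])))
        expect_equal(which(W[, k] == 1),
                     which(b$class_assignment == k))
      }
    }
  })

  # all prototypes assigned to class 1
  b1 <- prototype_bank(M = 2L, N = 3L, C = 2L, per_class_counts = c(3L, 0L),
                       K = 2L, init = "zero")
  W1 <- init_head_weights(b1)$weights
  expect_true(all(W1[, 1] == 1) && all(W1[, 2] == -0.5))
})

test_that("projection picks the nearest eligible patch with provenance", {
  C <- 2L
  bank <- make_bank(M = 1L, N = 2L, C = C,
                    vectors = matrix(c(0, 0, 5, 5), 2, C, byrow = TRUE))
  # two benign candidates: patches at distance 1 and 4 from prototype 1
  feats <- list(list(array(c(1, 2, 0, 0), c(2, 1, C))),   # patches (1,0), (2,0)
                list(array(c(5, 9, 5, 9), c(2, 1, C))))   # malignant sample
  labels <- c(0L, 1L)
  grades <- c("3", "5")
  ids <- c("Lb", "Lm")
  pb <- project_prototypes(bank, feats, labels, grades, ids,
                           candidate_policy(), c("bmode"))
  expect_equal(pb$vectors[1L, ], c(1, 0))        # distance 1 beats distance 4
  expect_equal(pb$vectors[2L, ], c(5, 5))        # exact match, distance 0
  expect_true(all(pb$provenance$projected))
  expect_equal(pb$provenance$lesion_id, c("Lb", "Lm"))
  expect_equal(pb$provenance$row[1L], 1L)

  # single candidate: prototype equals that patch (benign-only bank)
  bank_b <- prototype_bank(M = 1L, N = 2L, C = C, per_class_counts = c(2L, 0L),
                           init = "zero")
  one <- project_prototypes(bank_b, feats[1], 0L, "3", "Lb",
                            candidate_policy(), "bmode")
  expect_equal(one$vectors[1L, ], c(1, 0))
  expect_equal(one$vectors[2L, ], c(1, 0))

  # 4b lesions are never selected even when they are nearest
  feats4b <- c(feats, list(list(array(c(0, 0, 0, 0), c(2, 1, C)))))
  pb2 <- project_prototypes(bank, feats4b, c(0L, 1L, 0L), c("3", "5", "4b"),
                            c("Lb", "Lm", "L4b"), candidate_policy(), "bmode")
  expect_false("L4b" %in% pb2$provenance$lesion_id)
  # ... but an allow-all policy picks it (plain nearest patch of class)
  pb3 <- project_prototypes(bank, feats4b, c(0L, 1L, 0L), c("3", "5", "4b"),
                            c("Lb", "Lm", "L4b"), allow_all_policy("bmode"),
                            "bmode")
  expect_equal(pb3$provenance$lesion_id[1L], "L4b")

  # ties broken by lowest lesion_id in canonical order
  twin <- list(list(array(c(1, 1), c(1, 1, C)))
               , list(array(c(1, 1), c(1, 1, C))))
  pbt <- project_prototypes(prototype_bank(M = 1L, N = 2L, C = C,
                                           per_class_counts = c(2L, 0L),
                                           init = "zero"),
                            twin, c(0L, 0L), c("3", "3"), c("Lz", "La"),
                            candidate_policy(), "bmode")
  expect_equal(pbt$provenance$lesion_id[1L], "La")

  # empty candidate pool names the offending cell
  expect_error(project_prototypes(bank, feats[1], 0L, "4b", "Lb",
                                  candidate_policy(), "bmode"),
               "modality 'bmode', class 0")
})

test_that("learning-rate schedule follows the configured decay law", {
  cfg <- mupnet_config()
  expect_equal(vapply(c(1, 5, 6, 11, 41), lr_at_epoch, numeric(1), config = cfg),
               0.001 * 0.9^c(0, 0, 1, 2, 8))
  literal <- mupnet_config(lr_decay_factor = 0.1)
  expect_equal(lr_at_epoch(11, literal), 0.001 * 0.1^2)
  expect_equal(lr_at_epoch(41, literal), 0.001 * 0.1^8)
})

test_that("augmentation is joint, shape-preserving and seed-reproducible", {
  ds <- array_dataset(c(0L, 1L), size = 16L)
  s <- ds$samples[[1L]]
  # degenerate policy is the identity
  idp <- augmentation_policy(flip_prob = 0, rotation_range_deg = c(0, 0),
                             brightness_contrast_range = c(1, 1),
                             crop_fraction_range = c(1, 1))
  expect_equal(augment_sample(s, idp)$images, s$images)

  pol <- augmentation_policy()
  a1 <- withr::with_seed(21, augment_sample(s, pol))
  a2 <- withr::with_seed(21, augment_sample(s, pol))
  a3 <- withr::with_seed(22, augment_sample(s, pol))
  expect_identical(a1$images, a2$images)
  expect_false(identical(a1$images, a3$images))
  expect_equal(dim(a1$images$bmode), dim(s$images$bmode))

  # the same geometric transform is applied to every modality: a flip-only
  # policy must mirror all three images coherently
  flips <- augmentation_policy(flip_prob = 1, rotation_range_deg = c(0, 0),
                               brightness_contrast_range = c(1, 1),
                               crop_fraction_range = c(1, 1))
  af <- augment_sample(s, flips)
  for (mod in names(s$images))
    expect_equal(af$images[[mod]], s$images[[mod]][, 16:1, , drop = FALSE])
})

test_that("class balancing equalises counts with flagged augmented copies", {
  ds <- array_dataset(c(rep(0L, 7), rep(1L, 3)), size = 8L)
  bal <- balance_classes(ds, seed = 30L)
  expect_equal(as.vector(table(bal$manifest$label)), c(7L, 7L))
  expect_equal(sum(bal$manifest$augmented), 4L)
  # originals retained, copies pixel-wise different from their source
  expect_identical(bal$samples[1:10], ds$samples)
  cp <- bal$samples[[11L]]
  src <- ds$samples[[match(sub("_aug.*", "", cp$lesion_id), ds$manifest$lesion_id)]]
  expect_false(identical(cp$images, src$images))

  # already balanced input is returned unchanged
  even <- array_dataset(c(0L, 1L), size = 8L)
  expect_identical(balance_classes(even, seed = 1L), even)

  # the historical cohort imbalance: 817 benign / 335 malignant -> 817/817
  big <- array_dataset(c(rep(0L, 817), rep(1L, 335)), size = 2L)
  balanced <- balance_classes(big, seed = 31L)
  expect_equal(as.vector(table(balanced$manifest$label)), c(817L, 817L))
})

test_that("three-stage training freezes the right parameters per stage", {
  ds <- simulate_lesions(30, synth_config(image_size = 32L), seed = 40L)
  cfg1 <- mupnet_config(epochs_total = 1L, stage1_epochs = 1L,
                        stage3_epochs = 1L, batch_size = 8L,
                        n_prototypes = 2L,
                        backbone = backbone_config(channels = c(4L), C = 8L))
  cfg2 <- mupnet_config(epochs_total = 2L, stage1_epochs = 1L,
                        stage3_epochs = 1L, batch_size = 8L,
                        n_prototypes = 2L,
                        backbone = backbone_config(channels = c(4L), C = 8L))
  m1 <- mupnet_train(ds, cfg1, seed = 41L)
  m2 <- mupnet_train(ds, cfg2, seed = 41L)
  # stage 1 never touches the head: after a stage-1-only run the head still
  # carries the exact structured initialisation
  expect_true(all(m1$head$weights %in% c(1, -0.5)))
  # stage 3 never touches the extractors: adding a stage-3 epoch leaves
  # every extractor parameter bit-identical
  expect_identical(m1$extractors, m2$extractors)
  # ... but does tune the head away from the initialisation
  expect_false(all(m2$head$weights %in% c(1, -0.5)))
  expect_equal(m2$log$stage, c(1L, 3L))
})

test_that("training is reproducible and leaves a projected, logged model", {
  fit <- get_smoke_fit()
  m <- fit$model
  expect_s3_class(m, "mupnet")
  expect_equal(nrow(m$log), 16L)
  expect_true(all(m$log$lr == lr_at_epoch(m$log$epoch, m$config)))
  expect_true(all(m$bank$provenance$projected))
  expect_true(check_projection(m, fit$dataset))
  # every projected prototype's source grade obeys the candidate policy
  prov <- m$bank$provenance
  mods <- rep(m$modalities, each = m$bank$N)
  cls <- m$bank$class_assignment - 1L
  for (r in seq_len(nrow(prov)))
    expect_true(candidate_mask(prov$grade[r], cls[r], mods[r], cls[r],
                               m$policy))

  m2 <- mupnet_train(fit$dataset, smoke_config(), seed = 7L)
  expect_identical(m$head$weights, m2$head$weights)
  expect_identical(m$bank$vectors, m2$bank$vectors)
  expect_identical(m$extractors, m2$extractors)
})

test_that("training reduces the stage-1 objective on separable data", {
  fit <- get_smoke_fit()
  lg <- fit$model$log
  cyc <- fit$model$config$stage1_epochs + fit$model$config$stage3_epochs
  s1 <- lg[lg$stage == 1L, ]
  cycle <- (s1$epoch - 1L) %/% cyc
  expect_lt(mean(s1$total[cycle == max(cycle)]), mean(s1$total[cycle == 0L]))
})

test_that("projected prototypes come from archetypal lesions", {
  # the projection should favour lesions whose class-separating rendering
  # parameter is typical-to-extreme for the class, measured here as: the
  # mean parameter of malignant-prototype source lesions exceeds the mean
  # of benign-prototype source lesions, per modality cue
  fit <- get_smoke_fit()
  m <- fit$model
  ds <- fit$dataset
  par_of <- function(id, field) {
    p <- attr(ds$samples[[match(id, ds$manifest$lesion_id)]], "params")
    p[[field]]
  }
  fields <- c(bmode = "irregularity", doppler = "vessel_count",
              elasto = "stiffness_fraction")
  prov <- m$bank$provenance
  mods <- rep(m$modalities, each = m$bank$N)
  cls <- m$bank$class_assignment
  ok <- 0L; total <- 0L
  for (mod in m$modalities) {
    vals_m <- vapply(prov$lesion_id[mods == mod & cls == 2L],
                     par_of, numeric(1), field = fields[[mod]])
    vals_b <- vapply(prov$lesion_id[mods == mod & cls == 1L],
                     par_of, numeric(1), field = fields[[mod]])
    total <- total + 1L
    if (mean(vals_m) > mean(vals_b)) ok <- ok + 1L
  }
  expect_gte(ok, 2L)  # at least two of the three modality cues separate
})
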