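test_that("feature extraction obeys the shape contract and is deterministic", {
  withr::with_seed(1, {
    ext32 <- mupnet:::init_extractor(backbone_config(channels = c(4L, 8L, 8L, 16L, 16L),
                                                     C = 128L), 1L)
    img <- array(runif(224 * 224 * 3), c(224, 224, 3))
    fm <- extract_features(img, ext32)
    expect_equal(dim(fm), c(7L, 7L, 128L))

    ext8 <- mupnet:::init_extractor(backbone_config(), 2L)
    img64 <- array(runif(64 * 64 * 3), c(64, 64, 3))
    fm64 <- extract_features(img64, ext8)
    expect_equal(dim(fm64), c(8L, 8L, 128L))
    expect_identical(attr(fm64, "modality_index"), 2L)
    # odd sizes round up per pooling stage
    img50 <- array(runif(50 * 50 * 3), c(50, 50, 3))
    expect_equal(dim(extract_features(img50, ext8))[1:2], c(7L, 7L))

    expect_identical(extract_features(img64, ext8), fm64)  # determinism
  })
})

test_that("a zeroed extractor produces a constant feature map", {
  withr::with_seed(2, {
    ext <- mupnet:::init_extractor(backbone_config(channels = c(4L,  8L), C = 8L), 1L)
    ext$addon$W[] <- 0
    ext$addon$b[] <- 0
    fm <- extract_features(array(runif(16 * 16 * 3), c(16, 16, 3)), ext)
    # zero final-layer weights kill all input dependence; the logistic
    # squashing maps the zero pre-activation to a constant 1/2
    expect_true(all(fm == 0.5))
  })
})

test_that("similarity activation matches its closed form", {
  bank <- make_bank(M = 1L, N = 2L, C = 3L)
  bank$vectors[1L, ] <- c(1, 0, 0)
  # one position at distance 0 from prototype 1
  fm <- fmap1(0, 2, 2, 3)
  fm[1, 1, ] <- c(1, 0, 0)
  s <- similarity_scores(fm, bank, epsilon = 1e-4, top_k = 1L)
  expect_equal(s$scores[1L], log(1 / 1e-4), tolerance = 1e-9)

  # all positions at distance 1 (zero patches vs unit prototype)
  s1 <- similarity_scores(fmap1(0, 2, 2, 3), bank, 1e-4, 4L)
  expect_equal(s1$scores[1L], log(2 / (1 + 1e-4)), tolerance = 1e-9)

  # top-1 pooling equals the max over positions
  withr::with_seed(3, {
    fmr <- fmap1(runif(12), 2, 2, 3)
    sm <- similarity_scores(fmr, bank, 1e-4, 1L)
    expect_equal(sm$scores[1L], max(sm$activations[[1L]][, 1L]))
  })
})

test_that("similarity activation is strictly decreasing and vanishes at range", {
  d <- c(0, 10^seq(-4, 4, by = 0.25))
  a <- mupnet:::sim_activation(d, 1e-4)
  expect_true(all(diff(a) < 0))
  expect_true(all(mupnet:::sim_activation(c(1e4, 1e6), 1e-4) < 1e-3))
})

test_that("similarity agrees with the brute-force oracle on small maps", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      h <- sample(1:3, 1); w <- sample(1:3, 1); C <- sample(2:5, 1)
      N <- sample(2:4, 1)
      bank <- make_bank(M = 2L, N = N, C = C,
                        vectors = matrix(rnorm(2 * N * C), 2 * N, C))
      fms <- list(fmap1(rnorm(h * w * C), h, w, C, 1L),
                  fmap1(rnorm(h * w * C), h, w, C, 2L))
      k <- sample(seq_len(h * w), 1)
      got <- similarity_scores(fms, bank, 1e-4, k)$scores
      expect_equal(got, brute_similarity_multi(fms, bank, 1e-4, k),
                   tolerance = 1e-10)
    }
  })
})

test_that("similarity validates its inputs", {
  bank <- make_bank()
  expect_error(similarity_scores(fmap1(0, 2, 2, 3), bank, 1e-4, 5L), "top_k")
  expect_error(similarity_scores(fmap1(NaN, 2, 2, 3), bank, 1e-4, 1L),
               "non-finite")
  expect_error(similarity_scores(fmap1(0, 2, 2, 4), bank, 1e-4, 1L),
               "channels")
})

test_that("classification follows the structured head arithmetic", {
  bank <- make_bank(M = 1L, N = 2L, C = 3L)
  head <- init_head_weights(bank)
  # zero similarities: both logits zero, uniform probabilities
  cl0 <- classify(c(0, 0), head)
  expect_equal(cl0$logits, c(0, 0))
  expect_equal(cl0$prob, c(0.5, 0.5))

  # single malignant prototype firing with s = 2 under the init weights
  cl <- classify(c(0, 2), head)
  expect_equal(cl$logits, c(-1, 2))
  expect_equal(cl$p_malignant, exp(2) / (exp(2) + exp(-1)), tolerance = 1e-9)

  expect_error(classify(c(1, 2, 3), head), "length")
})

test_that("permuting prototypes together with head rows leaves logits unchanged", {
  withr::with_seed(5, {
    S <- runif(6)
    W <- matrix(rnorm(12), 6, 2)
    perm <- sample(6)
    l1 <- classify(S, classifier_head(W))$logits
    l2 <- classify(S[perm], classifier_head(W[perm, ]))$logits
    expect_equal(l1, l2)
  })
})

test_that("contribution scores decompose the logit", {
  bank <- make_bank(M = 1L, N = 2L, C = 3L)
  head <- init_head_weights(bank)
  expect_equal(contribution_scores(c(2, 0), head, 1L), c(2, 0))
  expect_equal(contribution_scores(c(2, 0), head, 2L), c(-1, 0))
  withr::with_seed(6, {
    S <- runif(10)
    W <- matrix(rnorm(20), 10, 2)
    h <- classifier_head(W)
    for (k in 1:2)
      expect_equal(sum(contribution_scores(S, h, k)), classify(S, h)$logits[k],
                   tolerance = 1e-6)
  })
  expect_error(contribution_scores(c(1, 0), head, 3L), "class")
})

test_that("classification is invariant to feature translation when top_k = 1", {
  withr::with_seed(7, {
    C <- 4L
    bank <- make_bank(M = 1L, N = 3L, C = C,
                      vectors = matrix(rnorm(3 * C), 3, C),
                      per_class_counts = c(2L, 1L))
    head <- init_head_weights(bank)
    fm <- array(rnorm(4 * 4 * C), c(4, 4, C))
    rolled <- fm[c(3, 4, 1, 2), c(2, 3, 4, 1), , drop = FALSE]
    l1 <- classify(similarity_scores(fmap1(fm, 4, 4, C), bank, 1e-4, 1L), head)
    l2 <- classify(similarity_scores(fmap1(rolled, 4, 4, C), bank, 1e-4, 1L), head)
    expect_equal(l1$logits, l2$logits, tolerance = 1e-12)
  })
})
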