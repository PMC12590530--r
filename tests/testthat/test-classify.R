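test_that("tiling is disjoint, complete, and falls back on oversize tiles", {
  img <- array(seq_len(512 * 512 * 3), c(512, 512, 3))
  tiles <- tile_image(img, 128)
  expect_length(tiles, 16)
  # union of tiles reconstructs the source exactly (pixel multiset equality)
  expect_equal(sort(unlist(lapply(tiles, as.vector))), sort(as.vector(img)))

  m <- matrix(1:256, 16, 16)
  quads <- split_map(m, 8)
  expect_length(quads, 4)
  expect_equal(sort(unlist(quads)), 1:256)

  small <- tile_image(matrix(1:16, 4, 4), 8)
  expect_length(small, 1)
  expect_equal(small[[1]], matrix(1:16, 4, 4))
})

test_that("augmentation attaches specimen ids and labels to every segment", {
  cohort <- simulate_classification_cohort(n_control = 2, n_case = 2,
                                           image_size = 128, seed = 3)
  segs <- augment_by_segmentation(cohort, image_tile = 64, map_sub = 8)
  expect_true(all(vapply(segs, function(s) nzchar(s$specimen_id), logical(1))))
  labs <- vapply(segs, `[[`, character(1), "label")
  ids <- vapply(segs, `[[`, character(1), "specimen_id")
  for (sp in cohort) {
    expect_true(all(labs[ids == sp$specimen_id] == sp$label))
  }
})

test_that("image features: constant tile, rotation mass conservation, contrast", {
  const <- matrix(5, 64, 64)
  f <- extract_image_features(const)
  expect_true(all(f[1:144] == 0))        # HOG block zero for zero gradients
  expect_length(f, 144 + 59)

  img <- simulate_polarized_image(0.2, 0.05, size = 64, seed = 2)$polarized
  f1 <- extract_image_features(img)
  rot <- img
  for (ch in 1:3) rot[, , ch] <- img[64:1, 64:1, ch]   # 180-degree rotation
  f2 <- extract_image_features(rot)
  expect_equal(sum(f2[145:203]), sum(f1[145:203]))     # LBP mass conserved

  # high- vs low-collagen tiles are linearly separable at n = 40
  set.seed(4)
  feats <- lapply(1:40, function(i) {
    frac <- if (i <= 20) 0.02 else 0.30
    extract_image_features(
      simulate_polarized_image(frac, frac / 3, size = 64)$polarized)
  })
  x <- do.call(rbind, feats)
  y <- rep(c("low", "high"), each = 20)
  m <- svm_train(x = x, y = y, kind = "linear", C = 100)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("AFM features: degenerate segment, order invariance, separability", {
  const_seg <- rep(2, 20)
  f <- extract_afm_features(const_seg)
  expect_equal(sum(f[1:16] > 0), 1)      # one occupied histogram bin
  expect_equal(unname(f[names(f) == "cv"]), 0)
  expect_error(extract_afm_features(rep(1, 10)), ">= 16")

  set.seed(6)
  v <- rlnorm(64, log(3), 0.5)
  expect_equal(extract_afm_features(v), extract_afm_features(rev(v)))

  # hep_weight 0.1 vs 0.4 segments separable with high CV accuracy
  set.seed(7)
  xs <- lapply(1:100, function(i) {
    w <- if (i <= 50) 0.1 else 0.4
    extract_afm_features(iid_mixture(64, 2, 0.25, 30, 0.3, w, seed = 700 + i))
  })
  x <- do.call(rbind, xs)
  y <- rep(c("lo", "hi"), each = 50)
  groups <- paste0("seg", seq_len(100))  # each segment its own group
  cv <- grouped_cv_train_eval(x, y, groups, kernel_spec("linear"),
                              k = 5, seed = 1)
  expect_gt(cv$mean_accuracy_pct, 90)
})

test_that("kernel closed forms", {
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(kernel_eval("rbf", x, x), 1)
  expect_equal(kernel_eval("linear", x, y), sum(x * y))
  expect_equal(kernel_eval("sigmoid", x, y, gamma = 0.5, coef0 = -1),
               tanh(0.5 * sum(x * y) - 1))
  # relu (arc-cosine order 1) on parallel vectors: theta = 0 -> |x||y|
  expect_equal(kernel_eval("relu", x, 2 * x), 2 * sum(x^2))
  # orthonormal basis -> identity Gram under the linear kernel
  B <- diag(4)
  G <- outer(1:4, 1:4, Vectorize(function(i, j) kernel_eval("linear", B[i, ], B[j, ])))
  expect_equal(G, diag(4))
  expect_error(kernel_eval("linear", 1:3, 1:4), "equal length")
})

test_that("Gram matrices are symmetric and PSD where required", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6)
  for (kind in c("linear", "rbf", "relu", "sigmoid")) {
    K <- nanomech:::gram_matrix(kind, X, gamma = 0.5, coef0 = 0)
    expect_equal(K, t(K), tolerance = 1e-10)
    if (kind != "sigmoid") {
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("grouped CV never leaks specimens and reports test accuracy", {
  cohort <- simulate_classification_cohort(n_control = 6, n_case = 6,
                                           maps_per_specimen = 2,
                                           image_size = 128, seed = 5)
  segs <- augment_by_segmentation(cohort, image_tile = 64, map_sub = 16)
  feats <- featurize_segments(segs)
  modality <- vapply(feats, `[[`, character(1), "modality")
  sm <- sample_matrix(feats[modality == "afm"])
  expect_warning(
    cv <- grouped_cv_train_eval(sm$x, sm$y, sm$groups,
                                kernel_spec("linear"), k = 20, seed = 2),
    "lowering k"
  )
  expect_equal(cv$k, 12)
  expect_equal(cv$accuracy_type, "test")
  # structural: every specimen sits in exactly one fold
  expect_equal(sort(names(cv$fold_of_specimen)), sort(unique(sm$groups)))
  expect_true(all(table(cv$fold_of_specimen) >= 1))
  # range endpoints are attained fold accuracies
  expect_true(all(cv$accuracy_range_pct %in% (100 * cv$fold_accuracy)))
})

test_that("perfectly separable cohorts reach a 100-100% range", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40 * 4, -5), 40, 4), matrix(rnorm(40 * 4, 5), 40, 4))
  y <- rep(c("a", "b"), each = 40)
  groups <- rep(sprintf("sp%02d", 1:20), each = 4)
  cv <- grouped_cv_train_eval(x, y, groups, kernel_spec("linear"),
                              k = 10, seed = 3)
  expect_equal(cv$accuracy_range_pct, c(100, 100))
})

test_that("label-permuted cohorts classify at chance", {
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(80 * 6), 80, 6)
    groups <- rep(sprintf("sp%02d", 1:20), each = 4)
    y_sp <- sample(rep(c("a", "b"), 10))          # specimen-level permuted
    y <- y_sp[match(groups, sprintf("sp%02d", 1:20))]
    grouped_cv_train_eval(x, y, groups, kernel_spec("linear"),
                          k = 10, seed = s)$mean_accuracy_pct
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("fusion concatenates blocks and self-fusion matches single modality", {
  cohort <- simulate_classification_cohort(n_control = 4, n_case = 4,
                                           maps_per_specimen = 2,
                                           image_size = 128, seed = 7)
  segs <- augment_by_segmentation(cohort, image_tile = 64, map_sub = 16)
  feats <- featurize_segments(segs)
  modality <- vapply(feats, `[[`, character(1), "modality")
  opt <- feats[modality == "optical"]; afm <- feats[modality == "afm"]
  fused <- fuse_modalities(opt, afm)
  expect_equal(length(fused[[1]]$features),
               length(opt[[1]]$features) + length(afm[[1]]$features))
  # 4 optical tiles vs 2 afm maps per specimen: 2 pairs, 2 dropped each
  expect_equal(attr(fused, "n_dropped"), 2L * 8L)

  self <- fuse_modalities(afm, afm)
  sm_self <- sample_matrix(self)
  sm_afm <- sample_matrix(afm)
  cv_self <- grouped_cv_train_eval(sm_self$x, sm_self$y, sm_self$groups,
                                   kernel_spec("linear"), k = 8, seed = 4)
  cv_afm <- grouped_cv_train_eval(sm_afm$x, sm_afm$y, sm_afm$groups,
                                  kernel_spec("linear"), k = 8, seed = 4)
  expect_lte(abs(cv_self$mean_accuracy_pct - cv_afm$mean_accuracy_pct),
             100 / cv_afm$k)

  # specimen in one modality only is excluded
  fused2 <- fuse_modalities(opt[-(1:4)], afm)
  expect_false(opt[[1]]$specimen_id %in%
                 vapply(fused2, `[[`, character(1), "specimen_id"))
})

test_that("external validation votes per specimen and flags ties", {
  set.seed(11)
  x <- rbind(matrix(rnorm(20 * 3, -4), 20, 3), matrix(rnorm(20 * 3, 4), 20, 3))
  y <- rep(c("control", "bleomycin"), each = 20)
  m <- svm_train(x = x, y = y, kind = "linear", C = 10)

  hold <- rbind(matrix(rnorm(8 * 3, -4), 8, 3), matrix(rnorm(8 * 3, 4), 8, 3))
  ids <- rep(c("h1", "h2"), each = 8)
  calls <- external_validate(m, hold, ids)
  expect_equal(calls$call[calls$specimen_id == "h1"], "control")
  expect_equal(calls$call[calls$specimen_id == "h2"], "bleomycin")
  expect_equal(calls$vote_fraction, c(1, 1))

  # forced tie
  tie_x <- rbind(matrix(-4, 2, 3), matrix(4, 2, 3))
  tie <- external_validate(m, tie_x, rep("t1", 4))
  expect_equal(tie$call, "indeterminate")
})

test_that("human-like holdout at larger effect is called correctly", {
  train <- simulate_classification_cohort(n_control = 8, n_case = 8,
                                          maps_per_specimen = 2,
                                          image_size = 128, seed = 21)
  hold <- simulate_classification_cohort(n_control = 1, n_case = 5,
                                         maps_per_specimen = 2, effect = 4,
                                         image_size = 128, seed = 22)
  featurize_afm <- function(cohort) {
    segs <- augment_by_segmentation(cohort, image_tile = 64, map_sub = 16)
    f <- featurize_segments(segs)
    f[vapply(f, `[[`, character(1), "modality") == "afm"]
  }
  tr <- sample_matrix(featurize_afm(train))
  te <- sample_matrix(featurize_afm(hold))
  m <- svm_train(x = tr$x, y = tr$y, kind = "linear", C = 1)
  calls <- external_validate(m, te$x, te$groups)
  fib <- calls[grepl("bleomycin", calls$specimen_id), ]
  expect_gte(mean(fib$call == "bleomycin"), 0.8)
})

test_that("optional PCA reduction trains and predicts consistently", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30 * 10, -2), 30, 10), matrix(rnorm(30 * 10, 2), 30, 10))
  y <- rep(c("a", "b"), each = 30)
  m <- svm_train(x = x, y = y, kind = "linear", C = 1, pca_dim = 3)
  expect_equal(ncol(m$x_train), 3)
  expect_equal(mean(predict(m, x) == y), 1)
})
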