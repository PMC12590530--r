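#' Split an image into non-overlapping tiles
#'
#' @param img Matrix or `c(h, w, 3)` array.
#' @param tile Tile side in pixels. Larger than the image -> single-segment
#'   fallback (the whole image).
#' @return List of tiles (same type as input), row-major order.
#' @export
tile_image <- function(img, tile = 64L) {
  dims <- dim(img)
  h <- dims[1]; w <- dims[2]
  if (tile > h || tile > w) return(list(img))
  nr <- h %/% tile; nc <- w %/% tile
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- (i - 1L) * tile + seq_len(tile)
    ci <- (j - 1L) * tile + seq_len(tile)
    out[[length(out) + 1L]] <- if (length(dims) == 3L) {
      img[ri, ci, , drop = FALSE]
    } else img[ri, ci, drop = FALSE]
  }
  out
}

#' Split an elasticity map into non-overlapping sub-grids
#'
#' @param map An [elasticity_map()] or numeric matrix of moduli.
#' @param sub Sub-grid side (e.g., 8 splits a 16 x 16 map into 4 quadrants).
#' @return List of numeric matrices (NA pixels retained).
#' @export
split_map <- function(map, sub = 8L) {
  m <- if (inherits(map, "elasticity_map")) {
    e <- map$E_kpa
    e[map$qc != "ok"] <- NA_real_
    e
  } else map
  tile_image(m, sub)
}

#' Segmentation-based data augmentation
#'
#' Partitions each specimen's images and AFM maps into non-overlapping
#' segments, each inheriting the specimen id and label, so that downstream
#' cross-validation can group by specimen. Deterministic given the tiling
#' configuration.
#'
#' @param specimens List; each element has `specimen_id`, `label`, and
#'   optionally `images` (list of RGB arrays) and/or `maps` (list of
#'   elasticity maps or modulus matrices).
#' @param image_tile Tile side for images (pixels).
#' @param map_sub Sub-grid side for maps.
#' @return List of `segment_sample`s: `specimen_id`, `label`, `modality`
#'   (`"optical"` or `"afm"`), `data`, `segment_index`.
#' @export
augment_by_segmentation <- function(specimens, image_tile = 64L, map_sub = 8L) {
  samples <- list()
  for (sp in specimens) {
    seg_i <- 0L
    for (img in sp$images %||% list()) {
      for (tl in tile_image(img, image_tile)) {
        seg_i <- seg_i + 1L
        samples[[length(samples) + 1L]] <- structure(
          list(specimen_id = sp$specimen_id, label = sp$label,
               modality = "optical", data = tl, segment_index = seg_i),
          class = "segment_sample")
      }
    }
    seg_i <- 0L
    for (mp in sp$maps %||% list()) {
      for (sg in split_map(mp, map_sub)) {
        seg_i <- seg_i + 1L
        samples[[length(samples) + 1L]] <- structure(
          list(specimen_id = sp$specimen_id, label = sp$label,
               modality = "afm", data = sg, segment_index = seg_i),
          class = "segment_sample")
      }
    }
  }
  samples
}

# ---- image features --------------------------------------------------------

#' Histogram-of-oriented-gradients + local-binary-pattern image features
#'
#' The tile is converted to grayscale, centrally cropped to a square,
#' intensity-normalized, and described by (i) a HOG over a `cells x cells`
#' grid with `bins` unsigned orientation bins, L2-normalized per cell, and
#' (ii) a 59-bin uniform 8-neighbor LBP histogram (normalized to sum 1, so
#' histogram mass is conserved under rotations of the tile). Constant tiles
#' yield an all-zero HOG block rather than an error.
#'
#' @param tile Matrix or RGB array.
#' @param cells HOG cells per side (default 4).
#' @param bins Orientation bins over 0-180 degrees (default 9).
#' @return Numeric feature vector of length `cells^2 * bins + 59`.
#' @export
extract_image_features <- function(tile, cells = 4L, bins = 9L) {
  gray <- if (length(dim(tile)) == 3L) {
    (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  } else tile
  side <- min(dim(gray))
  if (nrow(gray) != side || ncol(gray) != side) {   # central square crop
    r0 <- (nrow(gray) - side) %/% 2L
    c0 <- (ncol(gray) - side) %/% 2L
    gray <- gray[r0 + seq_len(side), c0 + seq_len(side)]
  }
  s <- stats::sd(gray)
  gray <- if (s > 0) (gray - mean(gray)) / s else gray * 0
  c(hog_features(gray, cells, bins), lbp_histogram(gray))
}

hog_features <- function(gray, cells = 4L, bins = 9L) {
  n <- nrow(gray)
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (gray[, 3:n] - gray[, 1:(n - 2)]) / 2
  gy[2:(n - 1), ] <- (gray[3:n, ] - gray[1:(n - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180          # unsigned orientation
  bin <- pmin(floor(ang / (180 / bins)) + 1L, bins)
  cell_of <- function(idx, n, cells) pmin((idx - 1L) %/% (n %/% cells) + 1L, cells)
  ci <- cell_of(row(gray), n, cells)
  cj <- cell_of(col(gray), n, cells)
  feat <- numeric(cells * cells * bins)
  idx <- ((ci - 1L) * cells + (cj - 1L)) * bins + bin
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  feat[as.integer(names(acc))] <- acc
  # L2 normalization per cell block
  dim(feat) <- c(bins, cells * cells)
  nrm <- sqrt(colSums(feat^2))
  nrm[nrm == 0] <- 1
  as.vector(sweep(feat, 2, nrm, "/"))
}

# uniform-pattern lookup for 8-bit LBP codes (<= 2 bit transitions).
lbp_uniform_map <- function() {
  codes <- 0:255
  transitions <- vapply(codes, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != c(bits[-1], bits[1]))
  }, integer(1))
  map <- integer(256)
  uniform <- which(transitions <= 2L)
  map[uniform] <- seq_along(uniform)      # 58 uniform patterns
  map[map == 0L] <- 59L                   # shared non-uniform bin
  map
}

lbp_histogram <- function(gray) {
  n <- nrow(gray); m <- ncol(gray)
  if (n < 3 || m < 3) return(numeric(59))
  ci <- 2:(n - 1); cj <- 2:(m - 1)
  center <- gray[ci, cj]
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                 c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, length(ci), length(cj))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- gray[ci + s[1], cj + s[2]]
    code <- code + as.integer(nb >= center) * 2L^(k - 1L)
  }
  map <- lbp_uniform_map()
  h <- tabulate(map[code + 1L], nbins = 59L)
  h / sum(h)
}

#' Fixed-length AFM feature vector
#'
#' Describes a set of Young's moduli (a map sub-grid or pooled spectrum) by a
#' 16-bin log10 histogram over a global range, the nine deciles, the median,
#' CV percent, and IQR. Invariant to the within-segment value order.
#'
#' @param values Numeric vector of moduli in kPa (or a matrix; NAs dropped).
#'   At least 16 finite values required.
#' @param log_range Global log10-kPa histogram range (default `c(-1, 3)`, i.e.
#'   0.1-1000 kPa; out-of-range values fall in the edge bins).
#' @param nbins Histogram bins (default 16).
#' @return Numeric feature vector of length `nbins + 12`.
#' @export
extract_afm_features <- function(values, log_range = c(-1, 3), nbins = 16L) {
  v <- as.numeric(values)
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 16) stop("AFM segment rejected: needs >= 16 moduli")
  lx <- pmin(pmax(log10(v), log_range[1]), log_range[2])
  edges <- seq(log_range[1], log_range[2], length.out = nbins + 1L)
  bin <- pmin(findInterval(lx, edges, rightmost.closed = TRUE), nbins)
  histo <- tabulate(bin, nbins) / length(v)
  deciles <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  c(histo, log10(deciles), median = log10(stats::median(v)),
    cv = 100 * stats::sd(v) / mean(v), iqr = stats::IQR(v))
}

# ---- kernels ---------------------------------------------------------------

#' Kernel specification for the SVM layer
#'
#' @param kind One of `"linear"`, `"relu"`, `"rbf"`, `"sigmoid"`. The
#'   "relu" kernel is the order-1 arc-cosine kernel
#'   k(x, y) = (1/pi) |x||y| (sin t + (pi - t) cos t) with t the angle
#'   between x and y: the positive-definite kernel whose feature map is a
#'   ReLU network layer.
#' @param C_grid Regularization grid searched during CV.
#' @param gamma_grid Kernel-width grid (rbf, sigmoid).
#' @param coef0_grid Offset grid (sigmoid).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "relu", "rbf", "sigmoid"),
                        C_grid = c(0.01, 0.1, 1, 10, 100),
                        gamma_grid = 10^seq(-3, 1),
                        coef0_grid = c(-1, 0, 1)) {
  kind <- match.arg(kind)
  if (any(C_grid <= 0)) stop("C must be > 0")
  if (any(gamma_grid <= 0)) stop("gamma must be > 0")
  structure(list(kind = kind, C_grid = C_grid, gamma_grid = gamma_grid,
                 coef0_grid = coef0_grid),
            class = "kernel_spec")
}

#' Evaluate a kernel on two vectors
#'
#' @param kind Kernel name (see [kernel_spec()]).
#' @param x,y Equal-length numeric vectors.
#' @param gamma,coef0 Kernel parameters where applicable.
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(kind, x, y, gamma = 1, coef0 = 0) {
  if (length(x) != length(y)) stop("kernel inputs must have equal length")
  switch(kind,
    linear = sum(x * y),
    rbf = exp(-gamma * sum((x - y)^2)),
    sigmoid = tanh(gamma * sum(x * y) + coef0),
    relu = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0) return(0)
      ct <- max(-1, min(1, sum(x * y) / (nx * ny)))
      t <- acos(ct)
      (1 / pi) * nx * ny * (sin(t) + (pi - t) * ct)
    },
    stop("unknown kernel: ", kind)
  )
}

# Gram matrix between rows of X and rows of Y.
gram_matrix <- function(kind, X, Y = X, gamma = 1, coef0 = 0) {
  dots <- tcrossprod(X, Y)
  switch(kind,
    linear = dots,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * dots
      exp(-gamma * pmax(d2, 0))
    },
    sigmoid = tanh(gamma * dots + coef0),
    relu = {
      nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
      nn <- outer(nx, ny)
      ct <- dots / ifelse(nn > 0, nn, 1)
      ct <- pmin(pmax(ct, -1), 1)
      t <- acos(ct)
      K <- (1 / pi) * nn * (sin(t) + (pi - t) * ct)
      K[nn == 0] <- 0
      K
    },
    stop("unknown kernel: ", kind)
  )
}

# ---- least-squares SVM -----------------------------------------------------

# Train a kernel least-squares SVM: solve
#   [0   1']   [b    ]   [0]
#   [1  K+I/C] [alpha] = [y]
# for labels y in {-1, +1}. Deterministic and convex.
lssvm_solve <- function(K, y, C) {
  n <- length(y)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- tryCatch(solve(M, c(0, y)),
                  error = function(e) solve(M + diag(n + 1) * 1e-8, c(0, y)))
  list(b = sol[1], alpha = sol[-1])
}

#' Train a kernel SVM classifier on segment samples
#'
#' Fits a least-squares support vector machine (LS-SVM): the standard SVM
#' hinge constraints are replaced by equality constraints, so training is a
#' single symmetric linear solve, deterministic for all four kernels.
#'
#' @param samples List of segment samples with `data` already converted to
#'   feature vectors, or a numeric feature matrix via `x`/`y` below.
#' @param x Feature matrix (rows = segments); alternative to `samples`.
#' @param y Labels (two classes).
#' @param kind Kernel name.
#' @param C,gamma,coef0 Kernel/regularization parameters.
#' @param standardize Standardize features using training statistics.
#' @param pca_dim Optional dimensionality reduction: project standardized
#'   features onto this many principal components (fitted on the training
#'   data only). `NULL` (the default) disables reduction.
#' @return An object of class `mechsvm` with a [predict.mechsvm()] method.
#' @export
svm_train <- function(samples = NULL, x = NULL, y = NULL, kind = "linear",
                      C = 1, gamma = 1, coef0 = 0, standardize = TRUE,
                      pca_dim = NULL) {
  if (!is.null(samples)) {
    x <- do.call(rbind, lapply(samples, function(s) s$features))
    y <- vapply(samples, function(s) s$label, character(1))
  }
  stopifnot(is.matrix(x), length(y) == nrow(x))
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2L) stop("svm_train needs exactly two classes")
  yy <- ifelse(as.character(y) == classes[2], 1, -1)
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) {
    s <- apply(x, 2, stats::sd); s[s == 0 | !is.finite(s)] <- 1; s
  } else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  rotation <- NULL
  if (!is.null(pca_dim)) {
    pca_dim <- min(pca_dim, ncol(xs), nrow(xs) - 1L)
    rotation <- stats::prcomp(xs, center = FALSE, scale. = FALSE)$rotation[
      , seq_len(pca_dim), drop = FALSE]
    xs <- xs %*% rotation
  }
  K <- gram_matrix(kind, xs, gamma = gamma, coef0 = coef0)
  fit <- lssvm_solve(K, yy, C)
  structure(
    list(kind = kind, C = C, gamma = gamma, coef0 = coef0,
         alpha = fit$alpha, b = fit$b, x_train = xs,
         center = ctr, scale = scl, rotation = rotation, classes = classes),
    class = "mechsvm"
  )
}

#' Predict classes for new feature rows
#' @param object A `mechsvm` model.
#' @param newdata Feature matrix (rows = segments).
#' @param decision Return the raw decision values instead of labels.
#' @param ... Unused.
#' @return Character vector of class labels (or numeric decision values).
#' @export
predict.mechsvm <- function(object, newdata, decision = FALSE, ...) {
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  if (!is.null(object$rotation)) xs <- xs %*% object$rotation
  K <- gram_matrix(object$kind, xs, object$x_train,
                   gamma = object$gamma, coef0 = object$coef0)
  f <- as.numeric(K %*% object$alpha + object$b)
  if (decision) return(f)
  ifelse(f >= 0, object$classes[2], object$classes[1])
}

# ---- grouped cross-validation ----------------------------------------------

#' Specimen-grouped k-fold cross-validation with grid search
#'
#' Partitions specimens (not segments) into k folds, so no specimen's
#' segments ever span the train/test boundary. Hyperparameters are chosen per
#' outer fold by an inner grouped 3-fold grid search on the training
#' specimens; the selected model is refit on all training segments and scored
#' on the held-out fold. Accuracies are test-fold accuracies by construction.
#'
#' @param features Feature matrix (rows = segments).
#' @param labels Segment labels (two classes).
#' @param specimen_ids Segment specimen ids (grouping variable).
#' @param kernel A [kernel_spec()].
#' @param k Folds (20 by default; lowered with a warning if there are fewer
#'   specimens).
#' @param seed Partition seed (recorded in the result).
#' @param inner_folds Inner grid-search folds (default 3).
#' @param pca_dim Optional per-fold PCA reduction (see [svm_train()]);
#'   disabled by default.
#' @return An object of class `cv_result`: `fold_accuracy` (fractions),
#'   `accuracy_range_pct` (min-max attained fold accuracies, percent),
#'   `mean_accuracy_pct`, `selected_params` (per fold), `fold_of_specimen`,
#'   `k`, `seed`, `accuracy_type = "test"`.
#' @export
grouped_cv_train_eval <- function(features, labels, specimen_ids,
                                  kernel = kernel_spec("linear"),
                                  k = 20L, seed = 1L, inner_folds = 3L,
                                  pca_dim = NULL) {
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(specimen_ids))
  specimens <- unique(specimen_ids)
  if (length(specimens) < k) {
    warning(sprintf("only %d specimen groups; lowering k from %d",
                    length(specimens), k))
    k <- length(specimens)
  }
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(k), length(specimens)))
  names(fold_of) <- specimens

  grid <- param_grid(kernel)
  fold_acc <- numeric(k)
  sel <- vector("list", k)
  for (fold in seq_len(k)) {
    test_spec <- specimens[fold_of == fold]
    tr <- !(specimen_ids %in% test_spec)
    te <- !tr
    stopifnot(!any(specimen_ids[tr] %in% specimen_ids[te]))  # leakage guard
    best <- select_params(features[tr, , drop = FALSE], labels[tr],
                          specimen_ids[tr], kernel$kind, grid, inner_folds)
    model <- svm_train(x = features[tr, , drop = FALSE], y = labels[tr],
                       kind = kernel$kind, C = best$C, gamma = best$gamma,
                       coef0 = best$coef0, pca_dim = pca_dim)
    pred <- predict(model, features[te, , drop = FALSE])
    fold_acc[fold] <- mean(pred == labels[te])
    sel[[fold]] <- best
  }
  structure(
    list(fold_accuracy = fold_acc,
         accuracy_range_pct = 100 * range(fold_acc),
         mean_accuracy_pct = 100 * mean(fold_acc),
         selected_params = sel,
         fold_of_specimen = fold_of,
         k = k, seed = seed, kernel = kernel$kind,
         accuracy_type = "test"),
    class = "cv_result"
  )
}

param_grid <- function(kernel) {
  switch(kernel$kind,
    linear = expand.grid(C = kernel$C_grid, gamma = 1, coef0 = 0),
    relu   = expand.grid(C = kernel$C_grid, gamma = 1, coef0 = 0),
    rbf    = expand.grid(C = kernel$C_grid, gamma = kernel$gamma_grid,
                         coef0 = 0),
    sigmoid = expand.grid(C = kernel$C_grid, gamma = kernel$gamma_grid,
                          coef0 = kernel$coef0_grid)
  )
}

# Inner grouped grid search; returns the grid row with the best mean inner
# validation accuracy (first on ties, so selection is reproducible).
select_params <- function(x, y, groups, kind, grid, inner_folds = 3L) {
  specs <- unique(groups)
  nf <- min(inner_folds, length(specs))
  if (nf < 2L || nrow(grid) == 1L) return(as.list(grid[1, ]))
  fold_of <- rep_len(seq_len(nf), length(specs))  # deterministic inner split
  names(fold_of) <- specs
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    a <- numeric(nf)
    for (f in seq_len(nf)) {
      hold <- specs[fold_of == f]
      tr <- !(groups %in% hold)
      if (length(unique(y[tr])) < 2L || !any(!tr)) { a[f] <- NA; next }
      m <- svm_train(x = x[tr, , drop = FALSE], y = y[tr], kind = kind,
                     C = grid$C[gi], gamma = grid$gamma[gi],
                     coef0 = grid$coef0[gi])
      a[f] <- mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[gi] <- mean(a, na.rm = TRUE)
  }
  as.list(grid[which.max(acc), ])
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s kernel, k = %d: accuracy %.1f-%.1f%% (mean %.1f%%), seed %d\n",
    x$kernel, x$k, x$accuracy_range_pct[1], x$accuracy_range_pct[2],
    x$mean_accuracy_pct, x$seed))
  invisible(x)
}

# ---- fusion and external validation ----------------------------------------

#' Fuse optical and AFM feature sets per specimen
#'
#' Pairs segments within each specimen by segment index and concatenates
#' block-standardized optical and AFM feature vectors. Each block is
#' standardized per feature and then scaled by the square root of its
#' dimension, so both modalities contribute equal total variance to the fused
#' vector regardless of feature count. Specimens present in only one
#' modality, and unpaired trailing segments, are dropped and counted.
#'
#' @param optical,afm Lists with elements `specimen_id`, `label`, `features`
#'   (numeric vector), `segment_index`.
#' @return A list of fused samples (modality `"fused"`), with attribute
#'   `n_dropped`.
#' @export
fuse_modalities <- function(optical, afm) {
  block_standardize <- function(samples) {
    X <- do.call(rbind, lapply(samples, `[[`, "features"))
    mu <- colMeans(X); s <- apply(X, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, s, "/") / sqrt(ncol(X))
    for (i in seq_along(samples)) samples[[i]]$features <- Xs[i, ]
    samples
  }
  optical <- block_standardize(optical)
  afm <- block_standardize(afm)
  ids_o <- vapply(optical, `[[`, character(1), "specimen_id")
  ids_a <- vapply(afm, `[[`, character(1), "specimen_id")
  shared <- intersect(unique(ids_o), unique(ids_a))
  dropped <- 0L
  fused <- list()
  for (sp in shared) {
    so <- optical[ids_o == sp]; sa <- afm[ids_a == sp]
    npair <- min(length(so), length(sa))
    dropped <- dropped + (length(so) - npair) + (length(sa) - npair)
    for (i in seq_len(npair)) {
      fused[[length(fused) + 1L]] <- list(
        specimen_id = sp, label = so[[i]]$label, modality = "fused",
        features = c(so[[i]]$features, sa[[i]]$features),
        segment_index = i
      )
    }
  }
  dropped <- dropped +
    sum(!(ids_o %in% shared)) + sum(!(ids_a %in% shared))
  attr(fused, "n_dropped") <- dropped
  fused
}

#' Specimen-level external validation by majority vote
#'
#' Applies a trained classifier to held-out specimens' segments and calls
#' each specimen by the majority class of its segment predictions. Exact ties
#' are flagged `"indeterminate"`, never silently broken.
#'
#' @param model A trained `mechsvm`.
#' @param features Feature matrix of held-out segments.
#' @param specimen_ids Specimen id per held-out segment.
#' @return A `data.frame`: `specimen_id`, `call`, `vote_fraction` (fraction
#'   of segments voting for the call), `n_segments`.
#' @export
external_validate <- function(model, features, specimen_ids) {
  pred <- predict(model, features)
  ids <- unique(specimen_ids)
  rows <- lapply(ids, function(sp) {
    p <- pred[specimen_ids == sp]
    tab <- table(p)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    call <- if (length(winners) > 1L) "indeterminate" else winners
    data.frame(specimen_id = sp, call = call,
               vote_fraction = top / length(p), n_segments = length(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
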