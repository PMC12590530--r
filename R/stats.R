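#' Median-center a sample of moduli
#'
#' Normalizes within-sample by the sample median. Moduli are positive and
#' compared on a fold scale, so the default divides by the median (the
#' resulting sample median is exactly 1); subtraction (resulting median 0) is
#' available by flag.
#'
#' @param values Positive numeric vector.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return Normalized values, with attributes `center` and `method` so the
#'   transform is invertible.
#' @export
median_center <- function(values, method = c("divide", "subtract")) {
  method <- match.arg(method)
  m <- stats::median(values)
  if (method == "divide") {
    if (!is.finite(m) || m == 0) stop("zero or non-finite sample median")
    out <- values / m
  } else {
    out <- values - m
  }
  attr(out, "center") <- m
  attr(out, "method") <- method
  out
}

#' Normalize values to the control-group mean
#' @param values Numeric vector.
#' @param control_mean Positive reference mean.
#' @return `values / control_mean`, with attribute `control_mean`.
#' @export
normalize_to_control <- function(values, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control_mean must be a positive finite number")
  }
  out <- values / control_mean
  attr(out, "control_mean") <- control_mean
  out
}

#' Z-score transform against a reference distribution
#' @param values Numeric vector.
#' @param ref_mean,ref_sd Reference mean and standard deviation (`ref_sd > 0`).
#' @return `(values - ref_mean) / ref_sd`, with the reference as attributes.
#' @export
zscore <- function(values, ref_mean = mean(values), ref_sd = stats::sd(values)) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stop("ref_sd must be > 0")
  out <- (values - ref_mean) / ref_sd
  attr(out, "ref_mean") <- ref_mean
  attr(out, "ref_sd") <- ref_sd
  out
}

#' ROUT outlier detection (constant model, Q = 1%)
#'
#' Identifies outliers in a univariate sample following the ROUT construction
#' restricted to a constant model: a robust center (the median), a robust
#' residual scale (RSDR: the 68.27th percentile of absolute residuals with an
#' n/(n - K) small-sample correction, K = 1 fitted parameter), t-ratios of
#' residuals against the RSDR, and a Benjamini-Hochberg sweep at rate `q`
#' over their two-sided t p-values, flagging the extreme points.
#'
#' @param values Numeric vector, n >= 10.
#' @param q Maximum desired false-outlier rate (0.01 = "Q = 1%").
#' @return An object of class `rout_result`: `inlier_mask`, `outlier_idx`,
#'   `rsdr`, `q`, `center`, `warning` (non-NULL when n < 10 and nothing was
#'   removed).
#' @export
rout_outliers <- function(values, q = 0.01) {
  n <- length(values)
  if (n < 10) {
    return(structure(
      list(inlier_mask = rep(TRUE, n), outlier_idx = integer(0),
           rsdr = NA_real_, q = q, center = stats::median(values),
           warning = "n < 10: ROUT skipped, no points removed"),
      class = "rout_result"
    ))
  }
  center <- stats::median(values)
  res <- values - center
  K <- 1L
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE, type = 7) *
    n / (n - K)
  if (rsdr <= 0) {
    # degenerate: majority of points identical; any deviation is an outlier
    p <- ifelse(res == 0, 1, 0)
  } else {
    tstat <- abs(res) / rsdr
    p <- 2 * stats::pt(tstat, df = n - K, lower.tail = FALSE)
  }
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  passed <- which(p[ord] <= thresh)
  outliers <- if (length(passed)) ord[seq_len(max(passed))] else integer(0)
  mask <- rep(TRUE, n)
  mask[outliers] <- FALSE
  structure(
    list(inlier_mask = mask, outlier_idx = sort(outliers), rsdr = rsdr,
         q = q, center = center, warning = NULL),
    class = "rout_result"
  )
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf("<rout_result> %d/%d flagged (Q = %g%%), RSDR = %.4g\n",
              length(x$outlier_idx), length(x$inlier_mask), 100 * x$q, x$rsdr))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Significance stars at the study's thresholds
#' @param p P-value(s).
#' @return `"****"` (p < 0.0001), `"***"` (p < 0.001), `"**"` (p < 0.01),
#'   `"*"` (p < 0.05), else `"ns"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Group comparison tests
#'
#' Two groups: unpaired Student's t-test when both groups pass Shapiro-Wilk
#' normality (p > 0.05), otherwise Mann-Whitney U. Three or more groups:
#' one-way ANOVA with Bonferroni-corrected pairwise t-tests when all groups
#' are normal, otherwise Kruskal-Wallis followed by Dunn's post hoc test
#' (rank-sum z, unadjusted by default).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length).
#' @param dunn_adjust P adjustment for Dunn comparisons: `"none"` (default)
#'   or `"bonferroni"`.
#' @return A `data.frame` report: `comparison`, `statistic`, `p`, `stars`,
#'   `method`, `n`.
#' @export
group_tests <- function(values, groups, dunn_adjust = c("none", "bonferroni")) {
  dunn_adjust <- match.arg(dunn_adjust)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  levels_ <- unique(groups)
  if (length(levels_) < 2L) stop("group_tests needs >= 2 groups")
  ns <- table(groups)
  if (any(ns < 3)) {
    bad <- names(ns)[ns < 3]
    return(data.frame(
      comparison = paste(bad, collapse = ","), statistic = NA_real_,
      p = NA_real_, stars = NA_character_,
      method = "skipped: group n < 3", n = sum(ns),
      stringsAsFactors = FALSE
    ))
  }
  normal <- vapply(levels_, function(g) {
    v <- values[groups == g]
    if (length(unique(v)) < 3 || length(v) > 5000) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }, logical(1))
  parametric <- all(normal)

  if (length(levels_) == 2L) {
    va <- values[groups == levels_[1]]; vb <- values[groups == levels_[2]]
    if (parametric) {
      tt <- stats::t.test(va, vb)
      res <- data.frame(comparison = paste(levels_, collapse = " vs "),
                        statistic = unname(tt$statistic), p = tt$p.value,
                        method = "t-test (unpaired)",
                        n = length(va) + length(vb), stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
      res <- data.frame(comparison = paste(levels_, collapse = " vs "),
                        statistic = unname(wt$statistic), p = wt$p.value,
                        method = "Mann-Whitney U",
                        n = length(va) + length(vb), stringsAsFactors = FALSE)
    }
  } else if (parametric) {
    fit <- stats::aov(values ~ factor(groups))
    p_global <- summary(fit)[[1]][["Pr(>F)"]][1]
    res <- data.frame(comparison = "omnibus",
                      statistic = summary(fit)[[1]][["F value"]][1],
                      p = p_global, method = "one-way ANOVA",
                      n = length(values), stringsAsFactors = FALSE)
    pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni")
    pm <- pw$p.value
    for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
      if (!is.na(pm[i, j])) {
        res <- rbind(res, data.frame(
          comparison = paste(rownames(pm)[i], "vs", colnames(pm)[j]),
          statistic = NA_real_, p = pm[i, j],
          method = "pairwise t (Bonferroni)",
          n = sum(groups %in% c(rownames(pm)[i], colnames(pm)[j])),
          stringsAsFactors = FALSE))
      }
    }
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    res <- data.frame(comparison = "omnibus",
                      statistic = unname(kw$statistic), p = kw$p.value,
                      method = "Kruskal-Wallis", n = length(values),
                      stringsAsFactors = FALSE)
    res <- rbind(res, dunn_test(values, groups, adjust = dunn_adjust))
  }
  res$stars <- significance_stars(res$p)
  res[, c("comparison", "statistic", "p", "stars", "method", "n")]
}

# Dunn's post hoc test: pairwise rank-sum z statistics on the pooled ranks
# with tie correction; unadjusted p by default.
dunn_test <- function(values, groups, adjust = "none") {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  levels_ <- unique(groups)
  rows <- list()
  for (i in seq_along(levels_)) for (j in seq_along(levels_)) {
    if (j <= i) next
    gi <- levels_[i]; gj <- levels_[j]
    ri <- mean(r[groups == gi]); rj <- mean(r[groups == gj])
    ni <- sum(groups == gi); nj <- sum(groups == gj)
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (ri - rj) / se
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste(gi, "vs", gj), statistic = z,
      p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      method = "Dunn post hoc", n = ni + nj, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") out$p <- pmin(1, out$p * nrow(out))
  out
}

#' Spearman rank correlation with exact small-n permutation p-value
#'
#' Computes rho = 1 - 6 sum(d^2) / (n (n^2 - 1)) on the ranks. For n <= 10
#' with no ties, the two-sided p-value is exact: the one-sided tail of the
#' permutation distribution of sum(d^2) (lower tail for positive rho, upper
#' for negative) is doubled and capped at 1. With ties, midrank rho with an
#' asymptotic t approximation is used and noted; the same approximation is
#' used for n > 10.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return An object of class `correlation_result`: `rho`, `p_two_sided`,
#'   `n`, `method`, `note`.
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("spearman_exact needs n >= 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(
      list(rho = NA_real_, p_two_sided = NA_real_, n = n,
           method = "undefined", note = "constant input: rho undefined"),
      class = "correlation_result"
    ))
  }
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  rho <- if (ties) {
    stats::cor(rx, ry)  # midrank (Pearson on ranks)
  } else {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  }
  if (!ties && n <= 10) {
    s_obs <- sum((rx - ry)^2)
    tail <- spearman_tail_count(n, s_obs, lower = rho >= 0)
    p <- min(1, 2 * tail / factorial(n))
    method <- "exact-permutation"
    note <- NULL
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "asymptotic"
    note <- if (ties) "ties present: midrank rho, asymptotic p" else NULL
  }
  structure(
    list(rho = rho, p_two_sided = p, n = n, method = method, note = note),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f, two-sided p = %.4g (n = %d, %s)\n",
              x$rho, x$p_two_sided, x$n, x$method))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Count permutations pi of 1..n with sum((pi - 1:n)^2) <= s (lower = TRUE) or
# >= s (lower = FALSE). Exhaustive, chunked by the first element so n = 10
# stays within memory.
spearman_tail_count <- function(n, s, lower = TRUE) {
  base <- seq_len(n)
  if (n <= 9) {
    P <- all_permutations(n)
    d2 <- colSums((P - base)^2)
    return(if (lower) sum(d2 <= s) else sum(d2 >= s))
  }
  P9 <- all_permutations(n - 1L)
  total <- 0
  for (first in base) {
    rest <- base[-first]
    Pn <- rbind(first, matrix(rest[P9], nrow = n - 1L))
    d2 <- colSums((Pn - base)^2)
    total <- total + if (lower) sum(d2 <= s) else sum(d2 >= s)
  }
  total
}

# All permutations of 1..n as an n x n! integer matrix (columns).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  Pm <- all_permutations(n - 1L)
  cols <- ncol(Pm)
  out <- matrix(0L, n, n * cols)
  for (pos in seq_len(n)) {
    block <- matrix(0L, n, cols)
    if (pos > 1L) block[seq_len(pos - 1L), ] <- Pm[seq_len(pos - 1L), , drop = FALSE]
    block[pos, ] <- n
    if (pos < n) block[(pos + 1L):n, ] <- Pm[pos:(n - 1L), , drop = FALSE]
    out[, (pos - 1L) * cols + seq_len(cols)] <- block
  }
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change = 2^-ddCt with
#' ddCt = (Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Positive quantification-cycle values.
#' @return A list: `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) stop("Ct values must be positive")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Per-timepoint Spearman correlation of collagen content and stiffness
#'
#' @param data `data.frame` with columns `specimen_id`, `collagen_fraction`,
#'   `mean_E_kpa`, `timepoint_days`.
#' @return A `data.frame`: one row per timepoint with `rho`, `p_two_sided`,
#'   `n`, `method`, `note` (`"skipped: n < 4"` or the constant-input flag
#'   where applicable).
#' @export
stage_correlation <- function(data) {
  stopifnot(all(c("specimen_id", "collagen_fraction", "mean_E_kpa",
                  "timepoint_days") %in% names(data)))
  tps <- sort(unique(data$timepoint_days))
  rows <- lapply(tps, function(tp) {
    d <- data[data$timepoint_days == tp, ]
    if (nrow(d) < 4) {
      return(data.frame(timepoint_days = tp, rho = NA_real_,
                        p_two_sided = NA_real_, n = nrow(d),
                        method = "skipped", note = "skipped: n < 4",
                        stringsAsFactors = FALSE))
    }
    r <- spearman_exact(d$collagen_fraction, d$mean_E_kpa)
    data.frame(timepoint_days = tp, rho = r$rho, p_two_sided = r$p_two_sided,
               n = r$n, method = r$method,
               note = r$note %||% "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
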