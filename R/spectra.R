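#' Pool a specimen's elasticity maps into an elasticity spectrum
#'
#' Collects all QC-passing moduli across a specimen's maps and summarizes the
#' distribution on the log10 scale: a Freedman-Diaconis histogram (density
#' normalized over the log domain) and a kernel density estimate with
#' Silverman's bandwidth. Pooling has set semantics: the map order is
#' irrelevant.
#'
#' @param maps List of [elasticity_map()] objects (or a single map).
#' @param specimen_id Optional identifier stored with the spectrum.
#' @return An object of class `elasticity_spectrum`: `values_kpa`, `n`,
#'   `hist` (edges, density on log10 kPa), `kde` (x, y, bw), `specimen_id`.
#' @export
pool_specimen <- function(maps, specimen_id = NULL) {
  if (inherits(maps, "elasticity_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "elasticity_map")))
  values <- unlist(lapply(maps, function(m) m$E_kpa[m$qc == "ok"]))
  values <- values[is.finite(values) & values > 0]
  values <- sort(values)   # order-invariant representation
  if (length(values) == 0L) {
    stop("empty spectrum: no pixels passed QC in the pooled maps")
  }
  lx <- log10(values)
  structure(
    list(
      values_kpa = values,
      n = length(values),
      hist = fd_histogram(lx),
      kde = if (length(values) >= 2L && stats::sd(lx) > 0) {
        den <- stats::density(lx, bw = "nrd0")
        list(x = den$x, y = den$y, bw = den$bw)
      } else NULL,
      specimen_id = specimen_id,
      n_maps = length(maps)
    ),
    class = "elasticity_spectrum"
  )
}

# Freedman-Diaconis histogram on the log10 domain; density integrates to 1.
fd_histogram <- function(lx) {
  n <- length(lx)
  iqr <- stats::IQR(lx)
  width <- if (n >= 2 && iqr > 0) 2 * iqr / n^(1 / 3) else 0.05
  lo <- min(lx); hi <- max(lx)
  if (hi - lo < width) hi <- lo + width
  edges <- seq(lo, hi + width, by = width)
  h <- graphics::hist(lx, breaks = edges, plot = FALSE, right = FALSE)
  list(edges = h$breaks, density = h$density, counts = h$counts)
}

#' @export
print.elasticity_spectrum <- function(x, ...) {
  cat(sprintf("<elasticity_spectrum> n = %d moduli from %d map(s)%s\n",
              x$n, x$n_maps,
              if (!is.null(x$specimen_id)) paste0(" [", x$specimen_id, "]") else ""))
  cat(sprintf("  median %.3g kPa, IQR %.3g kPa\n",
              stats::median(x$values_kpa), stats::IQR(x$values_kpa)))
  invisible(x)
}

#' @export
plot.elasticity_spectrum <- function(x, ...) {
  graphics::plot(x$kde$x, x$kde$y, type = "l",
                 xlab = "log10 Young's modulus (kPa)", ylab = "density", ...)
  invisible(x)
}

# ---- Gaussian mixture EM on log10(E) -------------------------------------

# Plain EM for a k-component univariate Gaussian mixture. Returns means, sds,
# weights, loglik, convergence flag. sd floor avoids spike collapse.
gmm_em <- function(x, k, mu0, sd0, w0, max_iter = 300, tol = 1e-8,
                   sd_floor = 1e-3) {
  n <- length(x)
  mu <- mu0; sd <- pmax(sd0, sd_floor); w <- w0 / sum(w0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    if (k == 1L) dens <- matrix(dens, ncol = 1L)
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) break  # empty component; give up on this start
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    sd <- pmax(sd, sd_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sd = sd, w = w, loglik = ll_old, converged = converged, k = k)
}

# Multi-start EM with deterministic + seeded random initializations.
gmm_fit <- function(x, k, n_starts = 5, seed = 1L) {
  n <- length(x)
  starts <- list()
  qs <- stats::quantile(x, probs = seq(0.5 / k, 1 - 0.5 / k, length.out = k),
                        names = FALSE)
  starts[[1]] <- list(mu = qs, sd = rep(stats::sd(x) / k + 1e-3, k),
                      w = rep(1 / k, k))
  if (n_starts > 1) {
    rng <- make_rng(seed)
    for (s in 2:n_starts) {
      mu0 <- sort(sample_rng(rng, x, k))
      starts[[s]] <- list(mu = mu0, sd = rep(stats::sd(x) / 2 + 1e-3, k),
                          w = rep(1 / k, k))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- gmm_em(x, k, st$mu, st$sd, st$w)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  best$bic <- -2 * best$loglik + (3 * k - 1) * log(n)
  best
}

# Local RNG stream that does not disturb the global seed.
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  env
}

sample_rng <- function(rng, x, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample(x, k)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out
}

#' Decompose an elasticity spectrum into LEP/HEP components
#'
#' Fits 1- and 2-component Gaussian mixtures to log10(E) by fixed-seed
#' multi-start EM and selects the component count by BIC. When two components
#' are kept they are labeled by their means: the lower one is the lower
#' elasticity peak (LEP, soft cell-dominated tissue), the higher one the
#' higher elasticity peak (HEP, collagen-dominated patches). Peak positions
#' are reported as component modes back-transformed to kPa (10^mean).
#' Heterogeneity metrics of the pooled values are attached.
#'
#' @param spectrum An [pool_specimen()] result with pooled n >= 50.
#' @param n_starts EM restarts per component count.
#' @param seed Seed for the EM restarts.
#' @return An object of class `nmf_summary`: `n_components`, `lep_mode_kpa`,
#'   `hep_mode_kpa` (NA if absent), `lep_weight`, `hep_weight`, `lep_log_sd`,
#'   `hep_log_sd`, `median_kpa`, `cv_percent`, `iqr_kpa`, `bic` (per k),
#'   `em_converged`, `fallback`.
#' @export
decompose_peaks <- function(spectrum, n_starts = 5, seed = 1L) {
  stopifnot(inherits(spectrum, "elasticity_spectrum"))
  if (spectrum$n < 50) stop("peak decomposition needs pooled n >= 50")
  x <- log10(spectrum$values_kpa)

  fit1 <- gmm_fit(x, 1L, n_starts = 1, seed = seed)
  fit2 <- gmm_fit(x, 2L, n_starts = n_starts, seed = seed)

  fallback <- FALSE
  if (!fit2$converged || !is.finite(fit2$bic)) {
    chosen <- fit1
    fallback <- TRUE
  } else {
    chosen <- if (fit2$bic < fit1$bic) fit2 else fit1
  }

  het <- heterogeneity_metrics(spectrum)
  if (chosen$k == 2L) {
    ord <- order(chosen$mu)
    mu <- chosen$mu[ord]; sdv <- chosen$sd[ord]; w <- chosen$w[ord]
    out <- list(
      n_components = 2L,
      lep_mode_kpa = 10^mu[1], hep_mode_kpa = 10^mu[2],
      lep_weight = w[1], hep_weight = w[2],
      lep_log_sd = sdv[1], hep_log_sd = sdv[2]
    )
  } else {
    out <- list(
      n_components = 1L,
      lep_mode_kpa = 10^chosen$mu[1], hep_mode_kpa = NA_real_,
      lep_weight = 1, hep_weight = 0,
      lep_log_sd = chosen$sd[1], hep_log_sd = NA_real_
    )
  }
  out$median_kpa <- het$median
  out$cv_percent <- het$cv_percent
  out$iqr_kpa <- het$iqr
  out$n <- spectrum$n
  out$bic <- c(k1 = fit1$bic, k2 = fit2$bic)
  out$em_converged <- c(k1 = fit1$converged, k2 = fit2$converged)
  out$fallback <- fallback
  out$specimen_id <- spectrum$specimen_id
  structure(out, class = "nmf_summary")
}

#' @export
print.nmf_summary <- function(x, ...) {
  cat(sprintf("<nmf_summary> %d component(s), n = %d%s\n", x$n_components,
              x$n,
              if (!is.null(x$specimen_id)) paste0(" [", x$specimen_id, "]") else ""))
  cat(sprintf("  LEP %.3g kPa (weight %.2f)", x$lep_mode_kpa, x$lep_weight))
  if (x$n_components == 2L) {
    cat(sprintf("; HEP %.3g kPa (weight %.2f)", x$hep_mode_kpa, x$hep_weight))
  }
  cat(sprintf("\n  median %.3g kPa, CV %.1f%%, IQR %.3g kPa\n",
              x$median_kpa, x$cv_percent, x$iqr_kpa))
  if (x$fallback) cat("  [EM fallback: single component]\n")
  invisible(x)
}

#' @export
coef.nmf_summary <- function(object, ...) {
  c(lep_mode_kpa = object$lep_mode_kpa, hep_mode_kpa = object$hep_mode_kpa,
    lep_weight = object$lep_weight, hep_weight = object$hep_weight)
}

#' Heterogeneity metrics of an elasticity spectrum
#'
#' Coefficient of variation (percent, sample sd over mean on the linear kPa
#' scale), interquartile range, quartiles, and median. Optionally applies
#' ROUT outlier removal first.
#'
#' @param spectrum An `elasticity_spectrum` (or a numeric vector of moduli).
#' @param rout Apply [rout_outliers()] at `q` before computing metrics.
#' @param q ROUT false-discovery rate (0.01 by default).
#' @return A list: `cv_percent`, `iqr`, `quartiles`, `median`, `n`,
#'   `rout_applied`, `n_outliers`.
#' @export
heterogeneity_metrics <- function(spectrum, rout = FALSE, q = 0.01) {
  values <- if (inherits(spectrum, "elasticity_spectrum")) {
    spectrum$values_kpa
  } else as.numeric(spectrum)
  if (length(values) < 2L) stop("heterogeneity metrics need n >= 2")
  n_out <- 0L
  if (rout) {
    rr <- rout_outliers(values, q = q)
    n_out <- length(rr$outlier_idx)
    values <- values[rr$inlier_mask]
  }
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  list(
    cv_percent = 100 * stats::sd(values) / mean(values),
    iqr = qs[3] - qs[1],
    quartiles = c(q1 = qs[1], q2 = qs[2], q3 = qs[3]),
    median = qs[2],
    n = length(values),
    rout_applied = rout,
    n_outliers = n_out
  )
}

#' Compare two elasticity spectra
#'
#' Median-centers each spectrum's pooled values (fold of sample median) and
#' compares the normalized distributions with a two-sided Mann-Whitney U
#' test; also reports the median shift (b minus a) and, optionally, the
#' difference of HEP modes from per-spectrum peak decomposition.
#'
#' @param spec_a,spec_b `elasticity_spectrum` objects.
#' @param normalize Normalization before testing: `"median_center"` or
#'   `"none"`.
#' @param decompose Also run [decompose_peaks()] on both (needs n >= 50).
#' @return A list: `p_value`, `u_statistic`, `median_shift`,
#'   `hep_mode_diff_kpa` (NA unless both bimodal), `n_a`, `n_b`.
#' @export
compare_spectra <- function(spec_a, spec_b, normalize = "median_center",
                            decompose = FALSE) {
  stopifnot(inherits(spec_a, "elasticity_spectrum"),
            inherits(spec_b, "elasticity_spectrum"))
  va <- spec_a$values_kpa; vb <- spec_b$values_kpa
  if (identical(normalize, "median_center")) {
    va <- median_center(va); vb <- median_center(vb)
  }
  wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
  hep_diff <- NA_real_
  if (decompose && spec_a$n >= 50 && spec_b$n >= 50) {
    da <- decompose_peaks(spec_a); db <- decompose_peaks(spec_b)
    if (da$n_components == 2L && db$n_components == 2L) {
      hep_diff <- db$hep_mode_kpa - da$hep_mode_kpa
    }
  }
  list(
    p_value = wt$p.value,
    u_statistic = unname(wt$statistic),
    median_shift = stats::median(spec_b$values_kpa) - stats::median(spec_a$values_kpa),
    median_shift_normalized = stats::median(vb) - stats::median(va),
    hep_mode_diff_kpa = hep_diff,
    n_a = spec_a$n, n_b = spec_b$n
  )
}
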