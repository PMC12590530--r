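#' Construct a force curve from raw channels
#'
#' @param z_nm Piezo displacement, nm, strictly monotone increasing along the
#'   approach, length >= 50.
#' @param deflection Deflection channel: nm if `calibrated = TRUE`, photodiode
#'   volts otherwise.
#' @param cantilever A [cantilever_model()].
#' @param calibrated Whether `deflection` is already in nm.
#' @param grid_position Optional `c(row, col)`.
#' @param truth Optional ground-truth list (see [simulate_force_curve()]).
#' @return A `force_curve` object.
#' @export
force_curve <- function(z_nm, deflection, cantilever = cantilever_model(),
                        calibrated = FALSE, grid_position = NULL, truth = NULL) {
  z_nm <- as.numeric(z_nm); deflection <- as.numeric(deflection)
  if (length(z_nm) != length(deflection)) stop("z and deflection lengths differ")
  if (length(z_nm) < 50) stop("force curves need >= 50 samples")
  if (any(diff(z_nm) <= 0)) stop("z must be strictly monotone increasing")
  out <- list(
    z_nm = z_nm,
    cantilever = cantilever,
    calibrated = isTRUE(calibrated),
    grid_position = grid_position,
    truth = truth
  )
  if (calibrated) {
    out$deflection_nm <- deflection
    out$force_nn <- cantilever$spring_constant * deflection
  } else {
    out$deflection_v <- deflection
  }
  structure(out, class = "force_curve")
}

#' Calibrate a raw force curve
#'
#' Converts the photodiode voltage into deflection (nm) via the optical-lever
#' sensitivity and into force (nN) via the spring constant
#' (`F_nN = k[N/m] * d[nm]`, since 1 N/m = 1 nN/nm). Idempotent on already
#' calibrated curves. Calibration constants must be supplied explicitly or be
#' present on the curve's cantilever; there are no silent defaults.
#'
#' @param curve A `force_curve`.
#' @param sensitivity Deflection sensitivity, nm/V; defaults to the curve's
#'   cantilever value.
#' @param spring_constant Spring constant, N/m; defaults to the curve's
#'   cantilever value.
#' @return The curve with `deflection_nm` and `force_nn` channels.
#' @export
calibrate <- function(curve, sensitivity = NULL, spring_constant = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (isTRUE(curve$calibrated)) return(curve)
  sensitivity <- sensitivity %||% curve$cantilever$deflection_sensitivity
  spring_constant <- spring_constant %||% curve$cantilever$spring_constant
  if (is.null(sensitivity) || !is.finite(sensitivity) || sensitivity <= 0) {
    stop("deflection sensitivity missing or invalid; calibration refused")
  }
  if (is.null(spring_constant) || !is.finite(spring_constant) ||
      spring_constant <= 0) {
    stop("spring constant missing or invalid; calibration refused")
  }
  if (is.null(curve$deflection_v)) stop("no raw voltage channel to calibrate")
  curve$deflection_nm <- curve$deflection_v * sensitivity
  curve$force_nn <- spring_constant * curve$deflection_nm
  curve$calibrated <- TRUE
  curve$cantilever$deflection_sensitivity <- sensitivity
  curve$cantilever$spring_constant <- spring_constant
  curve
}

#' Strip calibration from a curve (inverse of [calibrate()])
#' @param curve A calibrated `force_curve`.
#' @return The curve with a raw voltage channel only.
#' @export
decalibrate <- function(curve) {
  stopifnot(inherits(curve, "force_curve"), isTRUE(curve$calibrated))
  sens <- curve$cantilever$deflection_sensitivity
  curve$deflection_v <- curve$deflection_nm / sens
  curve$deflection_nm <- NULL
  curve$force_nn <- NULL
  curve$calibrated <- FALSE
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the tip-sample contact point of an approach curve
#'
#' Scans candidate split positions over a coarse-to-fine grid. For each
#' candidate the curve is modeled as {linear baseline before the split} +
#' {Sneddon cone response after the split}, and the split minimizing the total
#' squared deflection residual wins. The post-contact model regresses the
#' baseline-subtracted deflection x on the squared indentation
#' delta^2 = ((z - z0) - x)^2 through the origin, which is exact for the cone
#' forward model. If no split materially improves on an all-baseline linear
#' fit the curve is flagged as non-contact.
#'
#' @param curve A calibrated `force_curve` with at least 20 pre-contact
#'   samples.
#' @param min_pre Minimum samples kept before the split (default 20).
#' @param min_post Minimum samples kept after the split (default 10).
#' @param coarse Approximate number of coarse candidates scanned before
#'   refinement.
#' @param improvement_min Minimum fractional residual improvement over the
#'   all-baseline model required to accept contact (default 0.05).
#' @return A list: `z0_nm`, `d0_nm`, `index`, `baseline` (intercept, slope),
#'   `contact` (logical), `rss`.
#' @export
detect_contact_point <- function(curve, min_pre = 20L, min_post = 10L,
                                 coarse = 60L, improvement_min = 0.05) {
  stopifnot(inherits(curve, "force_curve"), isTRUE(curve$calibrated))
  z <- curve$z_nm; d <- curve$deflection_nm
  n <- length(z)
  lo <- as.integer(min_pre); hi <- n - as.integer(min_post)
  if (hi <= lo) stop("curve too short for contact-point detection")

  base_fit <- stats::lm.fit(cbind(1, z), d)
  rss_base <- sum(base_fit$residuals^2)
  if (rss_base < n * 1e-16) {
    return(list(z0_nm = NA_real_, d0_nm = NA_real_, index = NA_integer_,
                baseline = stats::coef(base_fit), contact = FALSE,
                rss = rss_base))
  }

  eval_split <- function(i) split_rss(z, d, i)
  step <- max(1L, (hi - lo) %/% as.integer(coarse))
  cand <- unique(c(seq(lo, hi, by = step), hi))
  rss <- vapply(cand, function(i) eval_split(i)$rss, numeric(1))
  best <- cand[which.min(rss)]
  fine <- seq(max(lo, best - step), min(hi, best + step))
  rss_f <- vapply(fine, function(i) eval_split(i)$rss, numeric(1))
  best <- fine[which.min(rss_f)]
  fit <- eval_split(best)

  improvement <- (rss_base - fit$rss) / rss_base
  contact <- is.finite(fit$rss) && improvement >= improvement_min &&
    fit$slope > 0
  list(
    z0_nm = if (contact) z[best] else NA_real_,
    d0_nm = if (contact) fit$d0 else NA_real_,
    index = if (contact) best else NA_integer_,
    baseline = fit$baseline,
    contact = contact,
    rss = fit$rss
  )
}

# Residual of the {baseline | cone} piecewise model split at index i.
split_rss <- function(z, d, i) {
  zl <- z[seq_len(i)]; dl <- d[seq_len(i)]
  bl <- stats::lm.fit(cbind(1, zl), dl)
  a <- bl$coefficients[1]; b <- bl$coefficients[2]
  rss_l <- sum(bl$residuals^2)

  zr <- z[(i + 1L):length(z)]; dr <- d[(i + 1L):length(z)]
  x <- dr - (a + b * zr)                  # baseline-subtracted deflection
  delta <- (zr - z[i]) - x                # indentation
  keep <- delta > 0
  if (sum(keep) < 3L) {
    return(list(rss = Inf, slope = -Inf, d0 = a + b * z[i],
                baseline = c(a, b)))
  }
  d2 <- delta[keep]^2
  slope <- sum(x[keep] * d2) / sum(d2^2)  # x = (A/k) delta^2 through origin
  res_r <- x - ifelse(keep, slope * delta^2, 0)
  list(rss = rss_l + sum(res_r^2), slope = slope, d0 = a + b * z[i],
       baseline = c(a, b))
}

#' Fit the Sneddon conical-indenter model to a force curve
#'
#' Estimates the Young's modulus from the approach segment by linear least
#' squares of force on squared indentation: with contact point (z0, d0) and
#' baseline-subtracted deflection x, the indentation is
#' delta = (z - z0) - x and the cone model predicts
#' F = (2/pi) tan(theta) E / (1 - nu^2) * delta^2, so E is the regression
#' slope divided by the geometric prefactor. Only post-contact samples with
#' delta >= 0 and F <= `force_cap_nn` enter the fit.
#'
#' @param curve A calibrated `force_curve`.
#' @param theta_deg Cone half-open angle, degrees (20 by default).
#' @param nu Poisson ratio (0.5, incompressible tissue).
#' @param force_cap_nn Maximum force used in the fit, nN (1.8 by default).
#' @param contact Optional result of [detect_contact_point()]; detected if
#'   missing.
#' @param min_post Minimum post-contact samples for a converged fit.
#' @return An object of class `sneddon_fit`: `E_kpa`, `E_pa`,
#'   `contact_point_z0`, `contact_deflection_d0`, `nu`, `theta`, `r_squared`,
#'   `max_indentation_nm`, `n_fit`, `converged`, `flag`.
#' @export
fit_sneddon <- function(curve, theta_deg = 20, nu = 0.5, force_cap_nn = 1.8,
                        contact = NULL, min_post = 10L) {
  stopifnot(inherits(curve, "force_curve"), isTRUE(curve$calibrated))
  if (is.null(contact)) contact <- detect_contact_point(curve)

  failed <- function(flag) {
    structure(
      list(E_kpa = NA_real_, E_pa = NA_real_,
           contact_point_z0 = contact$z0_nm,
           contact_deflection_d0 = contact$d0_nm,
           nu = nu, theta = theta_deg, r_squared = NA_real_,
           max_indentation_nm = NA_real_, n_fit = 0L,
           converged = FALSE, flag = flag),
      class = "sneddon_fit"
    )
  }
  if (!isTRUE(contact$contact)) return(failed("non_contact"))

  z <- curve$z_nm; d <- curve$deflection_nm
  k <- curve$cantilever$spring_constant
  a <- contact$baseline[1]; b <- contact$baseline[2]
  post <- z > contact$z0_nm
  x <- d[post] - (a + b * z[post])
  delta <- (z[post] - contact$z0_nm) - x
  force <- k * x
  keep <- delta >= 0 & force <= force_cap_nn
  if (sum(keep) < min_post) return(failed("too_few_post_contact"))

  d2 <- delta[keep]^2
  f <- force[keep]
  slope <- sum(f * d2) / sum(d2^2)              # nN / nm^2
  if (!is.finite(slope) || slope <= 0) return(failed("nonpositive_E"))

  prefactor <- (2 / pi) * tan(theta_deg * pi / 180) / (1 - nu^2) * 1e-6
  E_kpa <- slope / prefactor
  fitted <- slope * d2
  tss <- sum((f - mean(f))^2)
  r2 <- if (tss > 0) 1 - sum((f - fitted)^2) / tss else 1

  structure(
    list(E_kpa = E_kpa, E_pa = E_kpa * 1e3,
         contact_point_z0 = contact$z0_nm,
         contact_deflection_d0 = contact$d0_nm,
         nu = nu, theta = theta_deg,
         r_squared = max(0, min(1, r2)),
         max_indentation_nm = max(delta[keep]),
         n_fit = sum(keep),
         converged = TRUE, flag = "ok"),
    class = "sneddon_fit"
  )
}

#' @export
print.sneddon_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<sneddon_fit> E = %.4g kPa (theta = %g deg, nu = %g), R^2 = %.4f, n = %d\n",
      x$E_kpa, x$theta, x$nu, x$r_squared, x$n_fit))
    cat(sprintf("  contact at z0 = %.4g nm, max indentation %.4g nm\n",
                x$contact_point_z0, x$max_indentation_nm))
  } else {
    cat(sprintf("<sneddon_fit> not converged (%s)\n", x$flag))
  }
  invisible(x)
}

#' @export
coef.sneddon_fit <- function(object, ...) {
  c(E_kpa = object$E_kpa, z0_nm = object$contact_point_z0,
    d0_nm = object$contact_deflection_d0)
}

#' Predicted force at given indentation depths
#' @param object A `sneddon_fit`.
#' @param delta_nm Indentation depths, nm.
#' @param ... Unused.
#' @return Predicted force, nN.
#' @export
predict.sneddon_fit <- function(object, delta_nm, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  sneddon_prefactor(object$E_kpa, object$theta, object$nu) * delta_nm^2
}

#' @export
plot.sneddon_fit <- function(x, curve = NULL, ...) {
  if (is.null(curve)) stop("supply the fitted curve to plot")
  graphics::plot(curve$z_nm, curve$deflection_nm, type = "l",
                 xlab = "piezo z (nm)", ylab = "deflection (nm)", ...)
  if (x$converged) {
    graphics::abline(v = x$contact_point_z0, col = "red", lty = 2)
  }
  invisible(x)
}

#' Elasticity map container
#'
#' @param E_kpa Matrix of fitted Young's moduli, kPa (NA where rejected).
#' @param qc Character matrix of per-pixel QC codes (`"ok"` or a rejection
#'   reason).
#' @param pixel_size_um Pixel spacing, um.
#' @param provenance Free-form provenance list (specimen, map index, ...).
#' @param r_squared Optional matrix of per-pixel fit R^2.
#' @return An object of class `elasticity_map`.
#' @export
elasticity_map <- function(E_kpa, qc, pixel_size_um, provenance = list(),
                           r_squared = NULL) {
  stopifnot(is.matrix(E_kpa), is.matrix(qc), all(dim(E_kpa) == dim(qc)))
  n_rej <- sum(qc != "ok")
  structure(
    list(E_kpa = E_kpa, qc = qc, pixel_size_um = pixel_size_um,
         r_squared = r_squared, provenance = provenance,
         n_rejected = n_rej,
         usable = n_rej <= 0.5 * length(qc)),
    class = "elasticity_map"
  )
}

#' @export
print.elasticity_map <- function(x, ...) {
  cat(sprintf("<elasticity_map> %dx%d pixels (%.3g um), %d/%d pass QC%s\n",
              nrow(x$E_kpa), ncol(x$E_kpa), x$pixel_size_um,
              sum(x$qc == "ok"), length(x$qc),
              if (!x$usable) " [FLAGGED UNUSABLE]" else ""))
  invisible(x)
}

#' Fit every curve of a force map and assemble a QC-masked elasticity map
#'
#' Applies [fit_sneddon()] per pixel and rejects pixels that are non-contact,
#' non-converged, have non-positive modulus, or an F-vs-delta^2 R^2 below the
#' threshold. Maps with more than 50% rejected pixels are kept but flagged
#' unusable.
#'
#' @param fmap A `force_map` (see [simulate_force_map()]) or plain list of
#'   calibrated curves with `grid_position`s.
#' @param theta_deg,nu,force_cap_nn Fit parameters (see [fit_sneddon()]).
#' @param r2_min Minimum accepted R^2 (0.80 by default).
#' @param min_post Minimum post-contact samples.
#' @param provenance Provenance list stored on the result.
#' @return An [elasticity_map()].
#' @export
analyze_map <- function(fmap, theta_deg = 20, nu = 0.5, force_cap_nn = 1.8,
                        r2_min = 0.80, min_post = 10L, provenance = list()) {
  curves <- if (inherits(fmap, "force_map")) fmap$curves else fmap
  pixel_size <- if (inherits(fmap, "force_map")) fmap$pixel_size_um else NA_real_
  g <- as.integer(round(sqrt(length(curves))))
  stopifnot(g * g == length(curves))
  E <- matrix(NA_real_, g, g)
  qc <- matrix("ok", g, g)
  r2 <- matrix(NA_real_, g, g)
  for (idx in seq_along(curves)) {
    cv <- curves[[idx]]
    pos <- cv$grid_position %||% c((idx - 1L) %/% g + 1L, (idx - 1L) %% g + 1L)
    fit <- fit_sneddon(cv, theta_deg = theta_deg, nu = nu,
                       force_cap_nn = force_cap_nn, min_post = min_post)
    i <- pos[1]; j <- pos[2]
    if (!fit$converged) {
      qc[i, j] <- fit$flag
    } else if (fit$r_squared < r2_min) {
      qc[i, j] <- "low_r2"
      r2[i, j] <- fit$r_squared
    } else {
      E[i, j] <- fit$E_kpa
      r2[i, j] <- fit$r_squared
    }
  }
  elasticity_map(E, qc, pixel_size, provenance, r_squared = r2)
}
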