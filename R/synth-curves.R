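#' Simulate a single AFM force-displacement curve
#'
#' Forward model: a linear piezo approach ramp; before tip-sample contact the
#' deflection is a tilted, noisy baseline; after contact the cantilever load
#' k*(d - d0) balances the Sneddon cone response
#' F = (2/pi) tan(theta) E / (1 - nu^2) * delta^2 with indentation
#' delta = (z - z0) - (d - d0). The ramp terminates where the noiseless
#' deflection force reaches `max_force_nn`. Ground truth (modulus, contact
#' point, baseline) is recorded in the curve metadata.
#'
#' @param true_E_kpa Ground-truth Young's modulus in kPa (> 0).
#' @param cantilever A [cantilever_model()].
#' @param noise A [noise_model()].
#' @param max_force_nn Maximum applied loading force in nN (1.8 by default).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param n_samples Number of samples along the ramp (>= 50).
#' @param pre_contact_nm Nominal pre-contact travel before the true contact
#'   point, nm.
#' @param theta_deg,nu Cone half-angle (degrees) and Poisson ratio used by the
#'   forward model.
#' @param grid_position Optional `c(row, col)` position within a force map.
#' @return An object of class `force_curve` with fields `z_nm`,
#'   `deflection_nm`, `force_nn`, `cantilever`, `calibrated`, `truth`.
#' @export
simulate_force_curve <- function(true_E_kpa,
                                 cantilever = cantilever_model(),
                                 noise = noise_model(),
                                 max_force_nn = 1.8,
                                 seed = NULL,
                                 n_samples = 400L,
                                 pre_contact_nm = 2000,
                                 theta_deg = 20,
                                 nu = 0.5,
                                 grid_position = NULL) {
  if (!(is.numeric(true_E_kpa) && true_E_kpa > 0)) {
    stop("true_E_kpa must be a positive number")
  }
  if (!(max_force_nn > 0)) stop("max_force_nn must be > 0")
  if (n_samples < 50) stop("n_samples must be >= 50")
  if (!is.null(seed)) set.seed(as.integer(seed))

  k <- cantilever$spring_constant              # N/m == nN/nm
  A <- sneddon_prefactor(true_E_kpa, theta_deg, nu)  # nN per nm^2

  z0 <- pre_contact_nm +
    if (noise$contact_point_jitter_sd > 0) {
      stats::rnorm(1, 0, noise$contact_point_jitter_sd)
    } else 0
  z0 <- max(z0, pre_contact_nm * 0.25)

  delta_max <- sqrt(max_force_nn / A)          # indentation at the force cap
  x_max <- max_force_nn / k                    # deflection at the force cap
  z_end <- z0 + delta_max + x_max              # noiseless F reaches the cap here
  # sample grid includes z0 exactly (the discretization is ours to choose);
  # pre/post densities proportional to travel
  n_pre <- min(max(30L, round((n_samples - 1L) * z0 / z_end)), n_samples - 31L)
  n_post <- n_samples - 1L - n_pre
  z <- c(seq(0, z0, length.out = n_pre + 1L),
         seq(z0, z_end, length.out = n_post + 1L)[-1])

  x <- sneddon_deflection(z, z0, A, k)         # contact deflection, nm
  tilt <- noise$baseline_tilt / 1000           # nm per nm of travel
  baseline <- tilt * z
  d <- x + baseline
  if (noise$deflection_noise_sd > 0) {
    d <- d + stats::rnorm(n_samples, 0, noise$deflection_noise_sd)
  }

  structure(
    list(
      z_nm = z,
      deflection_nm = d,
      force_nn = k * d,                        # raw force channel; baseline handled at fit time
      cantilever = cantilever,
      calibrated = TRUE,
      grid_position = grid_position,
      truth = list(
        true_E_kpa = true_E_kpa,
        contact_z0_nm = z0,
        contact_d0_nm = tilt * z0,
        baseline_slope = tilt,
        theta_deg = theta_deg, nu = nu,
        max_force_nn = max_force_nn
      )
    ),
    class = "force_curve"
  )
}

# Noiseless contact deflection x = d - baseline for piezo positions z, solving
# k x = A ((z - z0) - x)^2 for the physical root (x < z - z0); 0 before contact.
sneddon_deflection <- function(z, z0, A, k) {
  s <- pmax(z - z0, 0)
  disc <- sqrt(4 * A * s * k + k^2)
  x <- (2 * A * s + k - disc) / (2 * A)
  x[s <= 0] <- 0
  x
}

#' @export
print.force_curve <- function(x, ...) {
  cal <- if (isTRUE(x$calibrated)) "calibrated (nm)" else "raw (V)"
  cat(sprintf("<force_curve> %d samples, %s, k = %.4g N/m\n",
              length(x$z_nm), cal, x$cantilever$spring_constant))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: E = %.4g kPa, z0 = %.4g nm\n",
                x$truth$true_E_kpa, x$truth$contact_z0_nm))
  }
  invisible(x)
}

#' Simulate a force-volume map
#'
#' Draws a per-pixel ground-truth modulus field from the two-component
#' lognormal mixture of a [tissue_mechanics_model()], with the stiff (HEP)
#' component realized as contiguous patches: a Gaussian-smoothed random field
#' is thresholded at the HEP weight quantile, so collagen appears as clusters
#' rather than salt-and-pepper pixels. One force curve is simulated per pixel.
#'
#' @param tissue A [tissue_mechanics_model()].
#' @param grid_points Grid points per side (16 -> 256 curves).
#' @param map_side_um Scan size in um (20 by default; pixel size =
#'   `map_side_um / grid_points`).
#' @param cantilever,noise,max_force_nn,n_samples Passed to
#'   [simulate_force_curve()].
#' @param seed Integer seed.
#' @param curves If `FALSE`, skip curve synthesis and return the true modulus
#'   field directly as an [elasticity_map] (fast path for downstream
#'   spectrum/classifier studies).
#' @return An object of class `force_map`: list of `force_curve`s (row-major),
#'   `true_E_kpa` matrix, `pixel_size_um`, and the generation parameters; or
#'   an `elasticity_map` when `curves = FALSE`.
#' @export
simulate_force_map <- function(tissue = stage_mechanics("control"),
                               grid_points = 16L,
                               map_side_um = 20,
                               cantilever = cantilever_model(),
                               noise = noise_model(),
                               max_force_nn = 1.8,
                               n_samples = 400L,
                               seed = NULL,
                               curves = TRUE) {
  stopifnot(inherits(tissue, "tissue_mechanics_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as.integer(grid_points)
  pixel_size <- map_side_um / g

  true_E <- sample_modulus_field(tissue, g)

  if (!curves) {
    return(elasticity_map(
      E_kpa = true_E,
      qc = matrix("ok", g, g),
      pixel_size_um = pixel_size,
      provenance = list(kind = "ground_truth", stage = tissue$stage_label)
    ))
  }

  curve_list <- vector("list", g * g)
  idx <- 1L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      curve_list[[idx]] <- simulate_force_curve(
        true_E_kpa = true_E[i, j], cantilever = cantilever, noise = noise,
        max_force_nn = max_force_nn, seed = NULL, n_samples = n_samples,
        grid_position = c(i, j)
      )
      idx <- idx + 1L
    }
  }
  structure(
    list(
      curves = curve_list,
      true_E_kpa = true_E,
      grid_points = g,
      pixel_size_um = pixel_size,
      map_side_um = map_side_um,
      tissue = tissue,
      cantilever = cantilever,
      noise = noise
    ),
    class = "force_map"
  )
}

# Spatially clustered mixture field: pixels whose smoothed random field falls
# above the (1 - hep_weight) quantile take the HEP component, so the empirical
# HEP fraction equals hep_weight up to rounding.
sample_modulus_field <- function(tissue, g) {
  n_hep <- round(tissue$hep_weight * g * g)
  field <- smooth_field(g, g, sigma = max(1, g / 8))
  hep_mask <- matrix(FALSE, g, g)
  if (n_hep > 0) {
    thr <- sort(field, decreasing = TRUE)[n_hep]
    hep_mask <- field >= thr
    # ties could over-select; trim deterministically
    if (sum(hep_mask) > n_hep) {
      extra <- which(hep_mask)[seq_len(sum(hep_mask) - n_hep)]
      hep_mask[extra] <- FALSE
    }
  }
  ln10 <- log(10)
  E <- matrix(0, g, g)
  n_lep <- sum(!hep_mask)
  if (n_lep > 0) {
    E[!hep_mask] <- 10^stats::rnorm(n_lep, log10(tissue$lep_mode_kpa),
                                    tissue$lep_log_sd)
  }
  if (n_hep > 0) {
    E[hep_mask] <- 10^stats::rnorm(sum(hep_mask), log10(tissue$hep_mode_kpa),
                                   tissue$hep_log_sd)
  }
  attr(E, "hep_mask") <- hep_mask
  E
}

# Gaussian-smoothed white-noise field (separable convolution, reflected edges).
smooth_field <- function(nr, nc, sigma = 2) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  f <- apply(f, 2, conv_reflect, kern = kern)
  t(apply(t(f), 2, conv_reflect, kern = kern))
}

conv_reflect <- function(v, kern) {
  half <- (length(kern) - 1L) / 2L
  n <- length(v)
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  idx <- pmin(pmax(idx, 1L), n)
  padded <- v[idx]
  as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
}

#' Simulate a full cohort of specimens
#'
#' Generates `maps_per_specimen` force maps for every specimen of every group
#' in a [study_design()], with stage-dependent mixture parameters from
#' [stage_mechanics()]. Fully reproducible from `design$seed`.
#'
#' @param design A [study_design()].
#' @param cantilever,noise Acquisition models shared by all specimens.
#' @param curves If `FALSE`, maps carry ground-truth modulus fields only
#'   (fast; suitable for spectrum and classifier studies).
#' @param n_samples Samples per simulated curve when `curves = TRUE`.
#' @return A list of class `cohort`: `specimens` (each with `specimen_id`,
#'   `stage_label`, `timepoint_days`, `sex`, `maps`), `design`, and a
#'   `manifest` data.frame.
#' @export
simulate_cohort <- function(design = study_design(),
                            cantilever = cantilever_model(),
                            noise = noise_model(),
                            curves = TRUE,
                            n_samples = 400L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  specimens <- list()
  rows <- list()
  sid <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    grp <- design$groups[gi, ]
    tissue <- stage_mechanics(grp$stage_label)
    for (si in seq_len(grp$n_specimens)) {
      sid <- sid + 1L
      specimen_id <- sprintf("%s_t%02d_s%02d", grp$stage_label,
                             grp$timepoint_days, si)
      maps <- lapply(seq_len(design$maps_per_specimen), function(mi) {
        simulate_force_map(
          tissue = tissue, grid_points = design$grid_points,
          map_side_um = design$map_side_um, cantilever = cantilever,
          noise = noise, curves = curves, n_samples = n_samples, seed = NULL
        )
      })
      specimens[[sid]] <- list(
        specimen_id = specimen_id,
        stage_label = grp$stage_label,
        timepoint_days = grp$timepoint_days,
        sex = grp$sex,
        maps = maps
      )
      rows[[sid]] <- data.frame(
        specimen_id = specimen_id, group = grp$stage_label,
        timepoint_days = grp$timepoint_days, sex = grp$sex,
        n_maps = design$maps_per_specimen, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(specimens = specimens, design = design,
         manifest = do.call(rbind, rows)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d specimens, %d maps each (%dx%d grid)\n",
              length(x$specimens), x$design$maps_per_specimen,
              x$design$grid_points, x$design$grid_points))
  print(table(x$manifest$group))
  invisible(x)
}
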