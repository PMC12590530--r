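#' Cantilever description
#'
#' Bundles the calibration constants of an AFM cantilever. Defaults follow a
#' soft silicon-nitride lever of the MLCT-Bio "D" type commonly used on lung
#' tissue: spring constant ~0.03 N/m, pyramidal tip with half-open angle
#' ~20 degrees, nominal tip radius 20 nm (metadata only; the indentation model
#' assumes an ideal cone).
#'
#' @param spring_constant Spring constant in N/m (equivalently nN/nm). Must be
#'   positive.
#' @param deflection_sensitivity Optical-lever sensitivity in nm/V, used to
#'   convert raw photodiode volts into nm of deflection.
#' @param half_open_angle_theta Half-open angle of the tip in degrees,
#'   strictly between 0 and 90.
#' @param tip_radius_nm Nominal tip radius in nm (metadata only).
#' @param resonance_khz Resonance frequency in kHz (metadata only).
#' @return An object of class `cantilever_model`.
#' @export
cantilever_model <- function(spring_constant = 0.03,
                             deflection_sensitivity = 50,
                             half_open_angle_theta = 20,
                             tip_radius_nm = 20,
                             resonance_khz = 15) {
  stopifnot(is.numeric(spring_constant), length(spring_constant) == 1L)
  if (!(spring_constant > 0)) stop("spring_constant must be > 0")
  if (!(deflection_sensitivity > 0)) stop("deflection_sensitivity must be > 0")
  if (!(half_open_angle_theta > 0 && half_open_angle_theta < 90)) {
    stop("half_open_angle_theta must be in (0, 90) degrees")
  }
  structure(
    list(
      spring_constant = spring_constant,
      deflection_sensitivity = deflection_sensitivity,
      half_open_angle_theta = half_open_angle_theta,
      tip_radius_nm = tip_radius_nm,
      resonance_khz = resonance_khz
    ),
    class = "cantilever_model"
  )
}

#' Two-component tissue elasticity model
#'
#' Describes a tissue region as a mixture of a soft, cell-dominated lognormal
#' component (the lower elasticity peak, LEP) and a stiff, collagen-dominated
#' lognormal component (the higher elasticity peak, HEP). Modes are the peak
#' positions on the kPa scale; spreads are standard deviations on the log10
#' scale.
#'
#' @param lep_mode_kpa Mode of the soft component in kPa.
#' @param lep_log_sd Log10-scale standard deviation of the soft component.
#' @param hep_mode_kpa Mode of the stiff component in kPa; must exceed
#'   `lep_mode_kpa` whenever `hep_weight > 0`.
#' @param hep_log_sd Log10-scale standard deviation of the stiff component.
#' @param hep_weight Mixing fraction of the stiff component, in `[0, 1]`.
#' @param stage_label One of `"control"`, `"inflammation_d3"`,
#'   `"transition_d14"`, `"chronic_d21"`, `"pirfenidone_preventive"`,
#'   `"pirfenidone_therapeutic"`.
#' @return An object of class `tissue_mechanics_model`.
#' @seealso [stage_mechanics()] for the stage-graded defaults.
#' @export
tissue_mechanics_model <- function(lep_mode_kpa = 2,
                                   lep_log_sd = 0.25,
                                   hep_mode_kpa = 30,
                                   hep_log_sd = 0.30,
                                   hep_weight = 0,
                                   stage_label = "control") {
  stages <- c("control", "inflammation_d3", "transition_d14", "chronic_d21",
              "pirfenidone_preventive", "pirfenidone_therapeutic")
  stage_label <- match.arg(stage_label, stages)
  if (!(lep_mode_kpa > 0 && hep_mode_kpa > 0)) stop("mixture modes must be > 0")
  if (hep_weight < 0 || hep_weight > 1) stop("hep_weight must be in [0, 1]")
  if (hep_weight > 0 && !(hep_mode_kpa > lep_mode_kpa)) {
    stop("hep_mode_kpa must exceed lep_mode_kpa when hep_weight > 0")
  }
  if (lep_log_sd <= 0 || hep_log_sd <= 0) stop("log-sds must be > 0")
  structure(
    list(
      lep_mode_kpa = lep_mode_kpa, lep_log_sd = lep_log_sd,
      hep_mode_kpa = hep_mode_kpa, hep_log_sd = hep_log_sd,
      hep_weight = hep_weight, stage_label = stage_label
    ),
    class = "tissue_mechanics_model"
  )
}

#' Stage-graded tissue mechanics defaults
#'
#' Default mixture parameters per disease stage of the intratracheal-bleomycin
#' model. HEP weight and HEP mode increase monotonically from control through
#' day 3 (inflammation), day 14 (transition) to day 21 (chronic fibrosis);
#' the pirfenidone arms revert toward control (the preventive arm suppresses
#' the HEP at day 14, the therapeutic arm removes most HEP mass at day 21).
#' Control lungs are unimodal (HEP weight 0), matching control elasticity
#' spectra that show a single soft peak; note the CV% of a lognormal mixture
#' is maximized by a RARE stiff component, so a nonzero control HEP weight
#' would invert the expected heterogeneity ordering. The kPa positions of the
#' peaks are configuration, not literature claims: soft lung parenchyma sits
#' around a ~2 kPa LEP and fibrillar collagen patches around a ~20-35 kPa HEP.
#'
#' @param stage Stage label (see [tissue_mechanics_model()]).
#' @return A `tissue_mechanics_model` for that stage.
#' @export
stage_mechanics <- function(stage = "control") {
  params <- switch(stage,
    control                 = list(w = 0.00, hep = 20),
    inflammation_d3         = list(w = 0.12, hep = 22),
    transition_d14          = list(w = 0.25, hep = 28),
    chronic_d21             = list(w = 0.40, hep = 35),
    pirfenidone_preventive  = list(w = 0.06, hep = 21),
    pirfenidone_therapeutic = list(w = 0.12, hep = 24),
    stop("unknown stage: ", stage)
  )
  tissue_mechanics_model(
    lep_mode_kpa = 2, lep_log_sd = 0.25,
    hep_mode_kpa = params$hep, hep_log_sd = 0.30,
    hep_weight = params$w, stage_label = stage
  )
}

#' Measurement noise model for simulated force curves
#'
#' @param deflection_noise_sd White noise on the deflection channel, nm.
#' @param baseline_tilt Linear drift of the pre-contact baseline, nm per um of
#'   piezo travel (an optical-lever artifact that persists under contact).
#' @param contact_point_jitter_sd Jitter of the true contact position across
#'   curves, nm.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(deflection_noise_sd = 0.5,
                        baseline_tilt = 1,
                        contact_point_jitter_sd = 20) {
  if (deflection_noise_sd < 0 || baseline_tilt < 0 || contact_point_jitter_sd < 0) {
    stop("noise parameters must be >= 0")
  }
  structure(
    list(
      deflection_noise_sd = deflection_noise_sd,
      baseline_tilt = baseline_tilt,
      contact_point_jitter_sd = contact_point_jitter_sd
    ),
    class = "noise_model"
  )
}

#' Zero-noise model (for oracle tests)
#' @return A `noise_model` with all components zero.
#' @export
noise_none <- function() noise_model(0, 0, 0)

#' Cohort study design
#'
#' The default mirrors the murine bleomycin study: 21 control mice (5 at day
#' 3, 10 at day 14, 6 at day 21), 23 bleomycin-treated mice (5/11/7), and 6
#' mice per pirfenidone arm; 10-15 force maps of 16 x 16 points over
#' 20 x 20 um per specimen.
#'
#' @param groups `data.frame` with columns `stage_label`, `n_specimens`,
#'   `timepoint_days`, `sex`.
#' @param maps_per_specimen Number of force maps per specimen (10-15 typical).
#' @param grid_points Grid points per map side (16 by default).
#' @param map_side_um Map side length in um (20 by default).
#' @param seed Integer seed controlling the whole cohort.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = default_study_groups(),
                         maps_per_specimen = 15,
                         grid_points = 16,
                         map_side_um = 20,
                         seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("stage_label", "n_specimens", "timepoint_days", "sex") %in%
                  names(groups)))
  if (any(groups$n_specimens < 1)) stop("n_specimens must be >= 1")
  if (maps_per_specimen < 1) stop("maps_per_specimen must be >= 1")
  if (grid_points < 1 || map_side_um <= 0) stop("invalid map geometry")
  structure(
    list(
      groups = groups,
      maps_per_specimen = as.integer(maps_per_specimen),
      grid_points = as.integer(grid_points),
      map_side_um = map_side_um,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' Default murine cohort group table
#' @return A `data.frame` of group definitions.
#' @export
default_study_groups <- function() {
  data.frame(
    stage_label = c("control", "control", "control",
                    "inflammation_d3", "transition_d14", "chronic_d21",
                    "pirfenidone_preventive", "pirfenidone_therapeutic"),
    n_specimens = c(5L, 10L, 6L, 5L, 11L, 7L, 6L, 6L),
    timepoint_days = c(3L, 14L, 21L, 3L, 14L, 21L, 14L, 21L),
    sex = "mixed",
    stringsAsFactors = FALSE
  )
}

# Sneddon prefactor for a rigid cone: F = (2/pi) tan(theta) / (1 - nu^2) * E * delta^2.
# With E in kPa and delta in nm this returns A such that F_nN = A * delta_nm^2.
sneddon_prefactor <- function(E_kpa, theta_deg = 20, nu = 0.5) {
  (2 / pi) * tan(theta_deg * pi / 180) / (1 - nu^2) * E_kpa * 1e-6
}

#' Closed-form Sneddon indentation depth at a given load
#'
#' delta = sqrt(F pi (1 - nu^2) / (2 tan(theta) E)); with the defaults and
#' E = 1 kPa the 1.8 nN cap is reached at ~2.41 um.
#'
#' @param force_nn Load in nN.
#' @param E_kpa Young's modulus in kPa.
#' @param theta_deg,nu Cone half-angle (degrees) and Poisson ratio.
#' @return Indentation depth in nm.
#' @export
sneddon_depth_at_force <- function(force_nn, E_kpa, theta_deg = 20, nu = 0.5) {
  sqrt(force_nn / sneddon_prefactor(E_kpa, theta_deg, nu))
}

#' Closed-form mean of a tissue elasticity mixture (kPa scale)
#'
#' Mean of the two-component lognormal mixture of a
#' [tissue_mechanics_model()], used as an analytic reference when comparing
#' stage configurations.
#'
#' @param tissue A `tissue_mechanics_model`.
#' @return Mixture mean in kPa.
#' @export
mixture_mean_kpa <- function(tissue) {
  ln10 <- log(10)
  m1 <- exp(log(tissue$lep_mode_kpa) + (tissue$lep_log_sd * ln10)^2 / 2)
  m2 <- exp(log(tissue$hep_mode_kpa) + (tissue$hep_log_sd * ln10)^2 / 2)
  (1 - tissue$hep_weight) * m1 + tissue$hep_weight * m2
}
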