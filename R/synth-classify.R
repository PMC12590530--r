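#' Simulate a two-arm cohort for classifier studies
#'
#' Emulates the in-silico biomarker experiment: control and bleomycin-treated
#' specimens, each carrying one polarized picrosirius-red image pair and one
#' AFM elasticity map. Disease severity acts on both modalities through a
#' shared specimen effect plus independent specimen-level noise per modality,
#' so the two channels are informative but only partially redundant - the
#' regime in which fusing them can improve classification.
#'
#' Latent model per specimen: severity s = `effect` for bleomycin, 0 for
#' control; the AFM channel sees `a = s + N(0,1)` mapped onto the specimen HEP
#' weight via plogis(-2 + 0.8 a), with additional map-to-map jitter of the
#' HEP weight on the logit scale (different regions of one lung differ); the
#' optical channel sees an independent `o = s + N(0,1)` mapped onto the
#' collagen I fraction via plogis(-2.5 + 0.8 o).
#'
#' @param n_control,n_case Specimens per arm (16 and 17 by default, matching
#'   the murine classification cohort).
#' @param effect Latent effect size in specimen-noise SD units (default 2.5,
#'   placing single-modality segment accuracies in the 70-90% regime).
#' @param maps_per_specimen AFM maps per specimen (default 4).
#' @param map_jitter_sd Map-level HEP-weight jitter on the logit scale.
#' @param image_size Polarized image side, pixels (default 256; four 128-px
#'   tiles).
#' @param grid_points AFM map side (16 by default).
#' @param seed Integer seed.
#' @return List of specimens, each with `specimen_id`, `label` (`"control"` /
#'   `"bleomycin"`), `images` (list with the polarized image), `brightfield`,
#'   `maps` (list of modulus matrices), and the latent truth.
#' @export
simulate_classification_cohort <- function(n_control = 16L, n_case = 17L,
                                           effect = 2.5,
                                           maps_per_specimen = 4L,
                                           map_jitter_sd = 0.9,
                                           image_size = 256L,
                                           grid_points = 16L, seed = 1L) {
  set.seed(as.integer(seed))
  specimens <- list()
  labels <- c(rep("control", n_control), rep("bleomycin", n_case))
  for (i in seq_along(labels)) {
    s <- if (labels[i] == "bleomycin") effect else 0
    a <- s + stats::rnorm(1)
    o <- s + stats::rnorm(1)
    hep_logit <- -2 + 0.8 * a
    col1 <- stats::plogis(-2.5 + 0.8 * o)
    col3 <- min(col1 / 3, 1 - col1)

    maps <- lapply(seq_len(maps_per_specimen), function(m) {
      w <- stats::plogis(hep_logit + stats::rnorm(1, 0, map_jitter_sd))
      tissue <- tissue_mechanics_model(
        lep_mode_kpa = 2, lep_log_sd = 0.25,
        hep_mode_kpa = 30, hep_log_sd = 0.30,
        hep_weight = w,
        stage_label = if (labels[i] == "bleomycin") "transition_d14" else "control"
      )
      simulate_force_map(tissue, grid_points = grid_points, curves = FALSE)
    })
    img <- simulate_polarized_image(col1, col3, size = image_size)
    specimens[[i]] <- list(
      specimen_id = sprintf("%s_%02d", labels[i], i),
      label = labels[i],
      images = list(img$polarized),
      brightfield = img$brightfield,
      maps = maps,
      truth = list(severity = s, afm_latent = a, optical_latent = o,
                   hep_weight = stats::plogis(hep_logit), col1_fraction = col1)
    )
  }
  specimens
}

#' Convert segment samples to feature samples
#'
#' Runs the modality-appropriate feature extractor over each segment produced
#' by [augment_by_segmentation()].
#'
#' @param segments List of `segment_sample`s.
#' @param ... Passed to the extractors.
#' @return List of samples with a `features` vector replacing `data`.
#' @export
featurize_segments <- function(segments, ...) {
  lapply(segments, function(s) {
    s$features <- if (s$modality == "optical") {
      extract_image_features(s$data, ...)
    } else {
      extract_afm_features(s$data)
    }
    s$data <- NULL
    s
  })
}

#' Assemble a feature matrix from feature samples
#' @param samples List with `features`, `label`, `specimen_id`.
#' @return List: `x` (matrix), `y` (labels), `groups` (specimen ids).
#' @export
sample_matrix <- function(samples) {
  list(
    x = do.call(rbind, lapply(samples, `[[`, "features")),
    y = vapply(samples, `[[`, character(1), "label"),
    groups = vapply(samples, `[[`, character(1), "specimen_id")
  )
}
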