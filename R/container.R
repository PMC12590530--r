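#' Write a specimen's force curves to a text container
#'
#' One directory per specimen holding the hierarchy specimen -> map -> curve:
#' a long-format CSV per map (`map_01.csv`, ... with columns `row`, `col`,
#' `z_nm`, `deflection_nm`) plus a JSON sidecar (`meta.json`) carrying the
#' cantilever constants, the generation seed/parameters, and per-curve ground
#' truth when available. Values round-trip exactly (shortest-accurate CSV
#' serialization).
#'
#' @param specimen List with `specimen_id` and `maps` (list of `force_map`s),
#'   e.g. one element of a [simulate_cohort()] result.
#' @param dir Parent directory; the container is `dir/<specimen_id>/`.
#' @return The container path, invisibly.
#' @export
write_curve_container <- function(specimen, dir) {
  path <- file.path(dir, specimen$specimen_id)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  truth_rows <- list()
  for (mi in seq_along(specimen$maps)) {
    fmap <- specimen$maps[[mi]]
    if (!inherits(fmap, "force_map")) stop("container needs curve-level maps")
    rows <- lapply(fmap$curves, function(cv) {
      # %.17g guarantees exact binary round-trip through the text container
      data.table::data.table(
        row = cv$grid_position[1], col = cv$grid_position[2],
        z_nm = sprintf("%.17g", cv$z_nm),
        deflection_nm = sprintf("%.17g", cv$deflection_nm)
      )
    })
    data.table::fwrite(data.table::rbindlist(rows),
                       file.path(path, sprintf("map_%02d.csv", mi)))
    truth_rows[[mi]] <- data.frame(
      map = mi,
      row = vapply(fmap$curves, function(cv) cv$grid_position[1], numeric(1)),
      col = vapply(fmap$curves, function(cv) cv$grid_position[2], numeric(1)),
      true_E_kpa = vapply(fmap$curves, function(cv) cv$truth$true_E_kpa, numeric(1)),
      contact_z0_nm = vapply(fmap$curves, function(cv) cv$truth$contact_z0_nm, numeric(1))
    )
  }
  first <- specimen$maps[[1]]
  meta <- list(
    specimen_id = specimen$specimen_id,
    stage_label = specimen$stage_label,
    timepoint_days = specimen$timepoint_days,
    sex = specimen$sex,
    n_maps = length(specimen$maps),
    grid_points = first$grid_points,
    pixel_size_um = first$pixel_size_um,
    map_side_um = first$map_side_um,
    cantilever = unclass(first$cantilever),
    noise = unclass(first$noise),
    tissue = unclass(first$tissue)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  data.table::fwrite(data.table::rbindlist(truth_rows),
                     file.path(path, "truth.csv"))
  invisible(path)
}

#' Read a specimen container written by [write_curve_container()]
#' @param path Container directory.
#' @return A specimen list with `force_map`s (curves calibrated, truth
#'   attached).
#' @export
read_curve_container <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  cant <- do.call(cantilever_model, meta$cantilever[
    c("spring_constant", "deflection_sensitivity", "half_open_angle_theta",
      "tip_radius_nm", "resonance_khz")])
  truth <- as.data.frame(data.table::fread(file.path(path, "truth.csv")))
  map_files <- sort(list.files(path, pattern = "^map_\\d+\\.csv$",
                               full.names = TRUE))
  maps <- lapply(seq_along(map_files), function(mi) {
    dt <- as.data.frame(data.table::fread(map_files[mi]))
    key <- paste(dt$row, dt$col)
    chunks <- split(seq_along(key), factor(key, levels = unique(key)))
    curves <- list()
    for (rows_idx in chunks) {
      sub <- dt[rows_idx, ]
      i <- sub$row[1]; j <- sub$col[1]
      trow <- truth[truth$map == mi & truth$row == i & truth$col == j, ]
      curves[[length(curves) + 1L]] <- force_curve(
        z_nm = sub$z_nm, deflection = sub$deflection_nm, cantilever = cant,
        calibrated = TRUE, grid_position = c(i, j),
        truth = if (nrow(trow)) list(true_E_kpa = trow$true_E_kpa,
                                     contact_z0_nm = trow$contact_z0_nm) else NULL
      )
    }
    structure(
      list(curves = curves, grid_points = meta$grid_points,
           pixel_size_um = meta$pixel_size_um, map_side_um = meta$map_side_um,
           cantilever = cant),
      class = "force_map"
    )
  })
  list(specimen_id = meta$specimen_id, stage_label = meta$stage_label,
       timepoint_days = meta$timepoint_days, sex = meta$sex, maps = maps)
}
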