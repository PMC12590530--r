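#' Read / write plain-text PPM images
#'
#' Images are numeric arrays `c(height, width, 3)` with 8-bit channel values
#' in 0-255. The plain (ASCII, "P3") portable-pixmap format keeps all fixtures
#' text-only.
#'
#' @param img Image array `c(h, w, 3)`, values 0-255.
#' @param path Output path.
#' @return `write_ppm`: the path, invisibly. `read_ppm`: the image array.
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  v <- as.integer(round(pmin(pmax(img, 0), 255)))
  h <- dim(img)[1]; w <- dim(img)[2]
  # interleave channels row-major: r g b r g b ...
  arr <- array(v, dim(img))
  flat <- integer(h * w * 3L)
  flat[seq(1, length(flat), by = 3)] <- t(arr[, , 1])
  flat[seq(2, length(flat), by = 3)] <- t(arr[, , 2])
  flat[seq(3, length(flat), by = 3)] <- t(arr[, , 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(flat, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tokens <- scan(text = paste(txt, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1] != "P3") stop("only plain (P3) PPM supported")
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  vals <- as.numeric(tokens[-(1:4)])
  stopifnot(length(vals) == h * w * 3L)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- matrix(vals[seq(1, length(vals), by = 3)], h, w, byrow = TRUE)
  img[, , 2] <- matrix(vals[seq(2, length(vals), by = 3)], h, w, byrow = TRUE)
  img[, , 3] <- matrix(vals[seq(3, length(vals), by = 3)], h, w, byrow = TRUE)
  img
}

# HSV channels of an RGB image array; h in [0, 360), s and v in [0, 1].
image_hsv <- function(img) {
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- dim(img)[1]; w <- dim(img)[2]
  list(h = matrix(hsv[1, ] * 360, h, w),
       s = matrix(hsv[2, ], h, w),
       v = matrix(hsv[3, ], h, w))
}

#' Paired brightfield / crossed-polarizer image set
#'
#' @param brightfield,polarized RGB arrays `c(h, w, 3)`, same shape, 0-255.
#' @param pixel_size_um Pixel size, um (metadata).
#' @param magnification Acquisition magnification (metadata).
#' @return An object of class `polarized_image_set`.
#' @export
polarized_image_set <- function(brightfield, polarized, pixel_size_um = NA_real_,
                                magnification = NA_real_) {
  stopifnot(identical(dim(brightfield), dim(polarized)),
            length(dim(brightfield)) == 3L)
  structure(
    list(brightfield = brightfield, polarized = polarized,
         pixel_size_um = pixel_size_um, magnification = magnification),
    class = "polarized_image_set"
  )
}

#' Segment tissue from a brightfield picrosirius-red image
#'
#' Tissue (pale yellow parenchyma or red collagen) is separated from the
#' near-white background by luminance/saturation thresholding, followed by
#' morphological hole filling (background components not connected to the
#' image border become tissue).
#'
#' @param brightfield RGB array, 0-255.
#' @param white_value_min Minimum HSV value for background (default 0.85).
#' @param white_sat_max Maximum HSV saturation for background (default 0.15).
#' @param fill_holes Fill enclosed background holes (default TRUE).
#' @return Logical matrix: TRUE = tissue. An empty mask is a valid result.
#' @export
segment_tissue <- function(brightfield, white_value_min = 0.85,
                           white_sat_max = 0.15, fill_holes = TRUE) {
  hsv <- image_hsv(brightfield)
  background <- hsv$v >= white_value_min & hsv$s <= white_sat_max
  if (fill_holes && any(background) && !all(background)) {
    background <- background & border_connected(background)
  }
  !background
}

# Flood fill from the border over TRUE pixels; returns pixels reachable from
# the border (4-connectivity), vectorized frontier propagation.
border_connected <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  frontier <- matrix(FALSE, nr, nc)
  frontier[1, ] <- mask[1, ]; frontier[nr, ] <- mask[nr, ]
  frontier[, 1] <- mask[, 1]; frontier[, nc] <- mask[, nc]
  reach <- frontier
  while (any(frontier)) {
    grown <- matrix(FALSE, nr, nc)
    grown[-1, ] <- grown[-1, ] | frontier[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | frontier[-1, ]
    grown[, -1] <- grown[, -1] | frontier[, -nc]
    grown[, -nc] <- grown[, -nc] | frontier[, -1]
    frontier <- grown & mask & !reach
    reach <- reach | frontier
  }
  reach
}

#' Quantify collagen I and III from a polarized picrosirius-red image pair
#'
#' Converts the crossed-polarizer image to HSV. Birefringent pixels (value at
#' least `value_min` of full scale) inside the brightfield tissue mask are
#' classified by hue: red-orange hues are collagen I (thick fibers), green
#' hues collagen III (thin fibers). Fractions are reported relative to tissue
#' area, not frame area; the two class masks are disjoint by construction.
#'
#' @param imageset A [polarized_image_set()].
#' @param hue_col1 Collagen I hue band(s), degrees: matrix-like
#'   `rbind(c(lo, hi), ...)`; default `[0, 45] U [315, 360)`.
#' @param hue_col3 Collagen III hue band, degrees; default `[75, 165]`.
#' @param value_min Brightness gate as a fraction of full scale (default 0.10).
#' @param tissue_mask Optional precomputed tissue mask.
#' @return An object of class `collagen_quantification`: `tissue_area_px`,
#'   `col1_fraction`, `col3_fraction`, `total_collagen_fraction`, `col1_mask`,
#'   `col3_mask`, `tissue_mask`, `saturated` flag, and the thresholds used.
#' @export
quantify_collagen_polarized <- function(imageset,
                                        hue_col1 = rbind(c(0, 45), c(315, 360)),
                                        hue_col3 = rbind(c(75, 165)),
                                        value_min = 0.10,
                                        tissue_mask = NULL) {
  stopifnot(inherits(imageset, "polarized_image_set"))
  if (is.null(tissue_mask)) tissue_mask <- segment_tissue(imageset$brightfield)
  hsv <- image_hsv(imageset$polarized)
  bright <- hsv$v >= value_min
  saturated <- mean(bright) > 0.95

  in_band <- function(hue, bands) {
    out <- matrix(FALSE, nrow(hue), ncol(hue))
    for (r in seq_len(nrow(bands))) {
      out <- out | (hue >= bands[r, 1] & hue < bands[r, 2])
    }
    out
  }
  col1 <- tissue_mask & bright & in_band(hsv$h, hue_col1)
  col3 <- tissue_mask & bright & in_band(hsv$h, hue_col3) & !col1
  ta <- sum(tissue_mask)
  structure(
    list(
      tissue_area_px = ta,
      col1_fraction = if (ta > 0) sum(col1) / ta else 0,
      col3_fraction = if (ta > 0) sum(col3) / ta else 0,
      total_collagen_fraction = if (ta > 0) (sum(col1) + sum(col3)) / ta else 0,
      col1_mask = col1, col3_mask = col3, tissue_mask = tissue_mask,
      saturated = saturated,
      thresholds = list(hue_col1 = hue_col1, hue_col3 = hue_col3,
                        value_min = value_min)
    ),
    class = "collagen_quantification"
  )
}

#' @export
print.collagen_quantification <- function(x, ...) {
  cat(sprintf(
    "<collagen_quantification> tissue %d px; collagen I %.3f, III %.3f (of tissue)%s\n",
    x$tissue_area_px, x$col1_fraction, x$col3_fraction,
    if (x$saturated) " [SATURATED FRAME]" else ""))
  invisible(x)
}

#' Simulate a picrosirius-red brightfield / polarized image pair
#'
#' Builds a smooth synthetic tissue section with known per-pixel classes:
#' background (white), plain tissue (pale yellow in brightfield, dark under
#' crossed polarizers), collagen I patches (red in brightfield, red-orange
#' birefringence) and collagen III patches (green birefringence). Collagen
#' fractions are exact pixel fractions of the tissue area; the ground-truth
#' class map is returned.
#'
#' @param col1_fraction,col3_fraction Target collagen fractions of tissue
#'   area, each in `[0, 1]` with sum <= 1.
#' @param size Image side, pixels.
#' @param tissue_fraction Fraction of the frame covered by tissue.
#' @param noise_sd Per-channel Gaussian pixel noise (8-bit units).
#' @param seed Integer seed.
#' @return A [polarized_image_set()] with extra fields `class_map`
#'   (0 background, 1 tissue, 2 collagen I, 3 collagen III) and `truth`
#'   (generating fractions).
#' @export
simulate_polarized_image <- function(col1_fraction, col3_fraction,
                                     size = 128L, tissue_fraction = 0.85,
                                     noise_sd = 3, seed = NULL) {
  if (col1_fraction < 0 || col1_fraction > 1 ||
      col3_fraction < 0 || col3_fraction > 1 ||
      col1_fraction + col3_fraction > 1) {
    stop("collagen fractions must lie in [0, 1] with sum <= 1")
  }
  if (tissue_fraction <= 0 || tissue_fraction > 1) {
    stop("tissue_fraction must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as.integer(size)

  # tissue is a central mass (background sea touches the frame border, as for
  # a section on a slide): smooth noise plus a radial bowl
  ctr <- (g + 1) / 2
  radial <- sqrt(outer((seq_len(g) - ctr)^2, (seq_len(g) - ctr)^2, "+")) / (g / 2)
  f_tissue <- smooth_field(g, g, sigma = g / 8) + 2 * (1 - radial)
  n_tissue <- round(tissue_fraction * g * g)
  tissue <- rank(-f_tissue, ties.method = "first") <= n_tissue
  tissue <- matrix(tissue, g, g)

  class_map <- matrix(0L, g, g)
  class_map[tissue] <- 1L
  t_idx <- which(tissue)
  n1 <- round(col1_fraction * length(t_idx))
  n3 <- round(col3_fraction * length(t_idx))
  f1 <- smooth_field(g, g, sigma = g / 16)
  if (n1 > 0) {
    sel1 <- t_idx[order(f1[t_idx], decreasing = TRUE)[seq_len(n1)]]
    class_map[sel1] <- 2L
  }
  if (n3 > 0) {
    f3 <- smooth_field(g, g, sigma = g / 16)
    rest <- t_idx[class_map[t_idx] == 1L]
    sel3 <- rest[order(f3[rest], decreasing = TRUE)[seq_len(min(n3, length(rest)))]]
    class_map[sel3] <- 3L
  }

  paint <- function(colors) {
    img <- array(0, c(g, g, 3))
    for (ch in 1:3) {
      pane <- matrix(colors[1, ch], g, g)
      for (cls in 1:3) pane[class_map == cls] <- colors[cls + 1, ch]
      img[, , ch] <- pane + stats::rnorm(g * g, 0, noise_sd)
    }
    pmin(pmax(img, 0), 255)
  }
  # rows: background, tissue, collagen I, collagen III
  bf <- paint(rbind(c(252, 252, 252),   # white background
                    c(235, 222, 170),   # pale yellow tissue
                    c(185, 60, 55),     # red collagen (both types stain red)
                    c(185, 70, 60)))
  pol <- paint(rbind(c(12, 12, 12),     # extinct background
                     c(16, 16, 16),     # non-birefringent tissue
                     c(230, 120, 30),   # red-orange collagen I
                     c(60, 200, 70)))   # green collagen III

  out <- polarized_image_set(bf, pol, pixel_size_um = 1, magnification = 10)
  out$class_map <- class_map
  out$truth <- list(col1_fraction = col1_fraction,
                    col3_fraction = col3_fraction,
                    tissue_fraction = tissue_fraction)
  out
}

#' Simulate a second-harmonic-generation image stack
#'
#' @param n_frames Number of raster scans (>= 1).
#' @param signal Underlying noise-free image (matrix); a default collagen-like
#'   pattern is generated when NULL.
#' @param noise_sd Additive iid Gaussian noise per frame.
#' @param size Side length for the default signal.
#' @param seed Integer seed.
#' @return An object of class `shg_stack`: `frames` (array h x w x n),
#'   `signal` (truth), `signal_mask`, `background_mask`, `noise_sd`.
#' @export
simulate_shg_stack <- function(n_frames, signal = NULL, noise_sd = 10,
                               size = 64L, seed = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(signal)) {
    f <- smooth_field(size, size, sigma = size / 10)
    signal <- 200 * (f > stats::quantile(f, 0.7))
  }
  h <- nrow(signal); w <- ncol(signal)
  frames <- array(0, c(h, w, n_frames))
  for (i in seq_len(n_frames)) {
    frames[, , i] <- signal +
      if (noise_sd > 0) stats::rnorm(h * w, 0, noise_sd) else 0
  }
  structure(
    list(frames = frames, signal = signal,
         signal_mask = signal > max(signal) / 2,
         background_mask = signal <= max(signal) / 2,
         noise_sd = noise_sd, n_frames = as.integer(n_frames)),
    class = "shg_stack"
  )
}

#' Average an SHG stack and estimate the signal-to-noise ratio
#'
#' The final image is the pixelwise mean of the frames. SNR is estimated as
#' mean over the signal region divided by the standard deviation over the
#' background region; a zero background spread (e.g., constant frames) yields
#' an infinite SNR with a flag.
#'
#' @param stack An `shg_stack` (or plain array h x w x n).
#' @param signal_mask,background_mask Logical matrices; default to the stack's
#'   ground-truth masks.
#' @return A list: `averaged` (matrix), `snr`, `snr_infinite` flag,
#'   `n_frames`.
#' @export
average_shg <- function(stack, signal_mask = NULL, background_mask = NULL) {
  frames <- if (inherits(stack, "shg_stack")) stack$frames else stack
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  if (inherits(stack, "shg_stack")) {
    signal_mask <- signal_mask %||% stack$signal_mask
    background_mask <- background_mask %||% stack$background_mask
  }
  avg <- apply(frames, c(1, 2), mean)
  if (is.null(signal_mask)) {
    thr <- stats::quantile(avg, 0.7)
    signal_mask <- avg > thr
    background_mask <- !signal_mask
  }
  bg_sd <- stats::sd(avg[background_mask])
  snr <- if (is.na(bg_sd) || bg_sd == 0) Inf else mean(avg[signal_mask]) / bg_sd
  list(averaged = avg, snr = snr, snr_infinite = !is.finite(snr),
       n_frames = dim(frames)[3])
}
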