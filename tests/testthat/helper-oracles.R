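# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (different algorithms, brute force where feasible).

# Brute-force Sneddon oracle: grid search over (z0, E) minimizing the sum of
# squared force residuals of the full forward model on a calibrated curve.
brute_force_sneddon <- function(curve, z0_range, E_range,
                                n_z0 = 61, n_E = 61, refine = 3) {
  k <- curve$cantilever$spring_constant
  z <- curve$z_nm
  d <- curve$deflection_nm
  f_meas <- k * d
  rss_of <- function(z0, E_kpa) {
    A <- (2 / pi) * tan(20 * pi / 180) / (1 - 0.5^2) * E_kpa * 1e-6
    s <- pmax(z - z0, 0)
    x <- (2 * A * s + k - sqrt(4 * A * s * k + k^2)) / (2 * A)
    x[s <= 0] <- 0
    sum((f_meas - k * x)^2)
  }
  for (r in seq_len(refine)) {
    z0s <- seq(z0_range[1], z0_range[2], length.out = n_z0)
    Es <- seq(E_range[1], E_range[2], length.out = n_E)
    rss <- outer(z0s, Es, Vectorize(rss_of))
    best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    bz <- z0s[best[1]]; bE <- Es[best[2]]
    dz <- diff(z0_range) / (n_z0 - 1); dE <- diff(E_range) / (n_E - 1)
    z0_range <- c(bz - dz, bz + dz)
    E_range <- c(max(bE - dE, 1e-6), bE + dE)
  }
  list(z0 = bz, E_kpa = bE)
}

# Independent exact Spearman tail: depth-first enumeration with running d^2,
# structurally unlike the package's permutation-matrix approach.
dfs_spearman_tail <- function(n, s_obs, lower = TRUE) {
  count <- 0L
  used <- rep(FALSE, n)
  recurse <- function(pos, acc) {
    if (pos > n) {
      hit <- if (lower) acc <= s_obs else acc >= s_obs
      if (hit) count <<- count + 1L
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (!used[v]) {
        used[v] <<- TRUE
        recurse(pos + 1L, acc + (v - pos)^2)
        used[v] <<- FALSE
      }
    }
  }
  recurse(1L, 0)
  count
}

# Convenience: quick elasticity map around a vector of modulus values.
values_as_map <- function(values, pixel_size = 1.25) {
  g <- ceiling(sqrt(length(values)))
  E <- matrix(NA_real_, g, g)
  E[seq_along(values)] <- values
  qc <- matrix("rejected_pad", g, g)
  qc[seq_along(values)] <- "ok"
  elasticity_map(E, qc, pixel_size)
}

# Lognormal mixture sampler independent of the package's spatially clustered
# field (iid pixels), for distribution-level oracles.
iid_mixture <- function(n, lep_mode, lep_sd, hep_mode, hep_sd, w, seed) {
  set.seed(seed)
  hep <- stats::runif(n) < w
  x <- numeric(n)
  x[!hep] <- 10^stats::rnorm(sum(!hep), log10(lep_mode), lep_sd)
  x[hep] <- 10^stats::rnorm(sum(hep), log10(hep_mode), hep_sd)
  x
}
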