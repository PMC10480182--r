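#' Voxel-sample a TKE profile (measurement resolution emulation)
#'
#' Emulates the finite spatial resolution of a 4D-flow-MRI TKE measurement:
#' the cut-plane lumen is tiled by voxels of edge `voxel_size_fraction`
#' times the reference diameter, and each voxel records the average of the
#' underlying TKE profile over its in-lumen extent (intravoxel averaging;
#' exact piecewise-linear integration). A trailing partial voxel averages
#' over its in-lumen portion only.
#'
#' @param profile a `plane_profile` (see [extract_plane_profile()]).
#' @param voxel_size_fraction voxel edge as a fraction of the reference
#'   diameter, in `(0, 1]`.
#' @return an object of class `tke_map`: voxel centres (m), per-voxel TKE,
#'   the voxel fraction, `snr = Inf` and `seed = NA` until noise is added.
#' @export
voxel_sample <- function(profile, voxel_size_fraction) {
  stopifnot(inherits(profile, "plane_profile"))
  if (voxel_size_fraction <= 0 || voxel_size_fraction > 1)
    stop("voxel_size_fraction must lie in (0, 1]")
  edge <- voxel_size_fraction * profile$diameter_ref
  lo <- profile$lumen[1]; hi <- profile$lumen[2]
  if (edge >= hi - lo) {
    warning("voxel larger than the lumen; returning a single-voxel map",
            call. = FALSE)
    edges <- c(lo, hi)
  } else {
    edges <- seq(lo, hi, by = edge)
    if (edges[length(edges)] < hi - 1e-12 * (hi - lo)) edges <- c(edges, hi)
  }
  nv <- length(edges) - 1
  centers <- numeric(nv); kv <- numeric(nv)
  for (m in seq_len(nv)) {
    a <- edges[m]; b <- edges[m + 1]
    centers[m] <- (a + b) / 2
    kv[m] <- piecewise_linear_mean(profile$positions, profile$k, a, b)
  }
  structure(list(voxel_centers = centers, k_values = kv,
                 voxel_size_fraction = voxel_size_fraction,
                 voxel_edge = edge, lumen = c(lo, hi),
                 diameter_ref = profile$diameter_ref,
                 snr = Inf, seed = NA_integer_, n_clipped = 0L),
            class = "tke_map")
}

# exact mean of the piecewise-linear interpolant of (x, y) over [a, b].
# The sample points are face midpoints, so the interpolant is extended
# linearly (from the outermost two samples) toward the lumen edges, matching
# a smooth underlying field up to the wall.
piecewise_linear_mean <- function(x, y, a, b) {
  n <- length(x)
  if (n >= 2) {
    if (a < x[1]) {
      sl <- (y[2] - y[1]) / (x[2] - x[1])
      y <- c(y[1] + sl * (a - x[1]), y)
      x <- c(a, x)
    }
    n <- length(x)
    if (b > x[n]) {
      sr <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      y <- c(y, y[n] + sr * (b - x[n]))
      x <- c(x, b)
    }
  }
  brk <- sort(unique(c(a, b, x[x > a & x < b])))
  vals <- approx(x, y, xout = brk, rule = 2, ties = "ordered")$y
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  sum(mids * diff(brk)) / (b - a)
}

#' Add Gaussian measurement noise to a TKE map
#'
#' Emulates measurement noise at a given signal-to-noise ratio: `SNR` is
#' defined as the maximum TKE of the map over the noise standard deviation,
#' so `sigma = max(k) / snr`. Independent zero-mean Gaussian perturbations
#' are added per voxel and resulting negative values are clipped to zero
#' (the clipped count is recorded in the map). `snr = Inf` returns the map
#' unchanged. Reproducible under a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param map a `tke_map`.
#' @param snr signal-to-noise ratio (positive, possibly `Inf`).
#' @param seed integer RNG seed.
#' @return the noisy `tke_map` (fields `snr`, `seed`, `n_clipped` updated).
#' @export
add_noise <- function(map, snr, seed) {
  stopifnot(inherits(map, "tke_map"))
  if (!is.numeric(snr) || is.na(snr) || snr <= 0)
    stop("snr must be positive (or Inf for noiseless)")
  if (is.infinite(snr)) return(map)
  sigma <- max(map$k_values) / snr
  noisy <- with_fixed_seed(seed, map$k_values + rnorm(length(map$k_values), 0, sigma))
  clipped <- sum(noisy < 0)
  map$k_values <- pmax(noisy, 0)
  map$snr <- snr
  map$seed <- as.integer(seed)
  map$n_clipped <- as.integer(clipped)
  map$sigma <- sigma
  map
}

#' Reconstruct an inlet TKE profile from a (degraded) map
#'
#' Piecewise-linear interpolation of the voxel values at the sub-model
#' inlet face midpoints, with constant extrapolation beyond the outermost
#' voxel centres; values are clamped to be non-negative. With voxel size
#' approaching the native face spacing and no noise the reconstruction
#' approaches the original profile (interpolation error `O(h^2)`).
#'
#' @param map a `tke_map` covering the inlet lumen.
#' @param submesh the sub-model `structured_mesh`.
#' @return numeric TKE profile at the `nj` inlet face midpoints.
#' @export
reconstruct_inlet_k <- function(map, submesh) {
  stopifnot(inherits(map, "tke_map"), inherits(submesh, "structured_mesh"))
  if (length(map$k_values) == 0) stop("empty TKE map")
  nj <- submesh$nj
  yt <- (submesh$yn[1, -1] + submesh$yn[1, -(nj + 1)]) / 2
  if (length(map$k_values) == 1) return(rep(max(map$k_values, 0), nj))
  pmax(approx(map$voxel_centers, map$k_values, xout = yt, rule = 2)$y, 0)
}

#' Full measurement-degradation pipeline for an inlet TKE profile
#'
#' Convenience wrapper: voxel-sample the profile, add noise at `snr`, and
#' reconstruct the TKE at the sub-model inlet faces.
#'
#' @param profile a `plane_profile`.
#' @param voxel_size_fraction voxel edge / reference diameter.
#' @param snr signal-to-noise ratio (`Inf` = noiseless).
#' @param seed integer RNG seed (ignored when `snr = Inf`).
#' @param submesh the sub-model `structured_mesh`.
#' @return list with the reconstructed `k` profile and the intermediate
#'   `map`.
#' @export
degrade_profile <- function(profile, voxel_size_fraction, snr, seed, submesh) {
  map <- voxel_sample(profile, voxel_size_fraction)
  map <- add_noise(map, snr, seed)
  list(k = reconstruct_inlet_k(map, submesh), map = map)
}

#' @export
print.tke_map <- function(x, ...) {
  cat(sprintf("TKE map: %d voxels (edge %g m = %g%% of D), SNR %s\n",
              length(x$k_values), x$voxel_edge, 100 * x$voxel_size_fraction,
              format(x$snr)))
  if (is.finite(x$snr))
    cat(sprintf("  sigma = %g, seed = %d, clipped %d voxel(s)\n",
                x$sigma, x$seed, x$n_clipped))
  invisible(x)
}

#' Serialize a TKE map to CSV (+ JSON sidecar)
#'
#' @param map a `tke_map`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_tke_map <- function(map, path) {
  stopifnot(inherits(map, "tke_map"))
  write.csv(data.frame(voxel_center = map$voxel_centers, k = map$k_values),
            path, row.names = FALSE)
  meta <- list(voxel_size_fraction = map$voxel_size_fraction,
               voxel_edge = map$voxel_edge, lumen = map$lumen,
               diameter_ref = map$diameter_ref,
               snr = if (is.finite(map$snr)) map$snr else "Inf",
               seed = map$seed, n_clipped = map$n_clipped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tke_map
#' @export
read_tke_map <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(voxel_centers = df$voxel_center, k_values = df$k,
                 voxel_size_fraction = meta$voxel_size_fraction,
                 voxel_edge = meta$voxel_edge, lumen = as.numeric(meta$lumen),
                 diameter_ref = meta$diameter_ref,
                 snr = if (identical(meta$snr, "Inf")) Inf else as.numeric(meta$snr),
                 seed = meta$seed, n_clipped = meta$n_clipped),
            class = "tke_map")
}
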