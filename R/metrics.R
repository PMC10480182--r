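#' Comparison region of interest
#'
#' Defines the ROI over which sub-model and ground-truth fields are
#' compared: an axial range measured from the sub-model inlet, the full
#' local lumen in the transverse direction, on a fixed deterministic sample
#' lattice. The default runs from 0.1D to 4D downstream of the inlet (the
#' small standoff avoids inlet-plane boundary artifacts) on a 64 x 32
#' lattice.
#'
#' @param geometry the `stenosis_geometry` (sets `D`).
#' @param start,end axial range in multiples of `D` downstream of the
#'   sub-model inlet.
#' @param n_axial,n_transverse lattice dimensions.
#' @return an object of class `comparison_roi`.
#' @export
comparison_roi <- function(geometry, start = 0.1, end = 4,
                           n_axial = 64, n_transverse = 32) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  if (end <= start) stop("ROI end must exceed its start")
  structure(list(start = start, end = end, n_axial = n_axial,
                 n_transverse = n_transverse, D = geometry$diameter_D),
            class = "comparison_roi")
}

# physical sample points of an ROI relative to a sub-model mesh:
# axial stations uniformly in [cut + start*D, cut + end*D], transverse
# midpoints spanning the local lumen (fractions independent of x)
roi_sample_points <- function(roi, mesh) {
  cut <- attr(mesh, "cut_offset") %||% mesh$axial_station[1]
  xs <- seq(cut + roi$start * roi$D, cut + roi$end * roi$D,
            length.out = roi$n_axial)
  L <- max(mesh$axial_station)
  if (xs[length(xs)] > L + 1e-12) stop("ROI extends beyond the domain outlet")
  tm <- -1 + (2 * seq_len(roi$n_transverse) - 1) / roi$n_transverse # (-1, 1)
  list(x = xs, tfrac = tm)
}

#' Sample a cell field on an ROI lattice
#'
#' Bilinear interpolation of a cell-centred field at the ROI sample points:
#' 1-D linear interpolation in the transverse coordinate within each
#' bracketing grid column, then linear in the axial coordinate (exact for
#' fields linear in x and y). Beyond the outermost cell centres the value
#' is held constant (toward walls and domain ends).
#'
#' @param field `ni x nj` matrix of cell values (or a `flow_field`
#'   component).
#' @param mesh the `structured_mesh` the field lives on.
#' @param roi a [comparison_roi()].
#' @return numeric matrix `n_axial x n_transverse` of sampled values.
#' @export
sample_field_on_roi <- function(field, mesh, roi) {
  stopifnot(inherits(mesh, "structured_mesh"), inherits(roi, "comparison_roi"))
  pts <- roi_sample_points(roi, mesh)
  xs <- pts$x; tm <- pts$tfrac
  xc <- (mesh$axial_station[-1] + mesh$axial_station[-(mesh$ni + 1)]) / 2
  if (xs[1] < mesh$axial_station[1] - 1e-12) stop("ROI starts upstream of the domain")
  out <- matrix(0, length(xs), length(tm))
  # transverse fractions of cell centres (same for every column)
  tc <- (mesh$tbrk[-1] + mesh$tbrk[-(mesh$nj + 1)]) / 2
  tq <- if (mesh$mode == "axisymmetric") abs(tm) else tm
  for (a in seq_along(xs)) {
    x <- xs[a]
    i2 <- findInterval(x, xc, all.inside = TRUE)
    i2 <- min(max(i2, 1), mesh$ni - 1)
    w <- (x - xc[i2]) / (xc[i2 + 1] - xc[i2])
    w <- min(max(w, 0), 1)
    col1 <- approx(tc, field[i2, ], xout = tq, rule = 2)$y
    col2 <- approx(tc, field[i2 + 1, ], xout = tq, rule = 2)$y
    out[a, ] <- (1 - w) * col1 + w * col2
  }
  out
}

#' Mean absolute error
#'
#' `mean(|sub - ori|)` over matched sample points; symmetric, zero iff the
#' value lists are identical.
#'
#' @param values_sub,values_ori equal-length numeric vectors (or matrices).
#' @return scalar MAE.
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 1)) # 1
#' @export
mae <- function(values_sub, values_ori) {
  a <- as.numeric(values_sub); b <- as.numeric(values_ori)
  if (length(a) != length(b)) stop("value lists must have equal length")
  if (length(a) < 1) stop("at least one sample is required")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  mean(abs(a - b))
}

#' Maximum absolute error
#'
#' As [mae()] but with the maximum instead of the mean.
#' @inheritParams mae
#' @return scalar maximum absolute error.
#' @export
max_abs_error <- function(values_sub, values_ori) {
  a <- as.numeric(values_sub); b <- as.numeric(values_ori)
  if (length(a) != length(b)) stop("value lists must have equal length")
  if (length(a) < 1) stop("at least one sample is required")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  max(abs(a - b))
}

#' Error summary of a sub-model solution against the ground truth
#'
#' Samples velocity magnitude `sqrt(U^2 + V^2)` and TKE of both solutions
#' on the ROI lattice and reports MAE, maximum error, and MAE as a
#' percentage of the ground-truth field maximum over the ROI (the
#' percent-of-maximum normalization convention).
#'
#' @param flow_sub sub-model `flow_field`.
#' @param flow_ori ground-truth `flow_field` (full model).
#' @param mesh_sub,mesh_ori the corresponding meshes.
#' @param roi a [comparison_roi()] anchored at the sub-model inlet.
#' @return an object of class `error_summary` (also a one-row data.frame):
#'   `mae_velocity`, `mae_tke`, `max_err_velocity`, `max_err_tke`,
#'   `mae_velocity_pct_of_max`, `mae_tke_pct_of_max`, `n`.
#' @export
summarize_errors <- function(flow_sub, flow_ori, mesh_sub, mesh_ori, roi) {
  vmag_sub <- sqrt(flow_sub$u^2 + flow_sub$v^2)
  vmag_ori <- sqrt(flow_ori$u^2 + flow_ori$v^2)
  # anchor the ROI at the sub-model inlet for both meshes
  cut <- attr(mesh_sub, "cut_offset") %||% mesh_sub$axial_station[1]
  sv <- sample_field_on_roi(vmag_sub, mesh_sub, roi)
  sk <- sample_field_on_roi(flow_sub$k, mesh_sub, roi)
  ov <- sample_roi_at(vmag_ori, mesh_ori, roi, cut)
  ok <- sample_roi_at(flow_ori$k, mesh_ori, roi, cut)
  vmax <- max(abs(ov)); kmax <- max(abs(ok))
  out <- data.frame(
    mae_velocity = mae(sv, ov), mae_tke = mae(sk, ok),
    max_err_velocity = max_abs_error(sv, ov), max_err_tke = max_abs_error(sk, ok),
    n = length(sv))
  out$mae_velocity_pct_of_max <- 100 * out$mae_velocity / vmax
  out$mae_tke_pct_of_max <- 100 * out$mae_tke / kmax
  class(out) <- c("error_summary", "data.frame")
  out
}

# sample a field of an arbitrary mesh on the ROI lattice anchored at `cut`
sample_roi_at <- function(field, mesh, roi, cut) {
  fake <- mesh
  attr(fake, "cut_offset") <- cut
  sample_field_on_roi(field, fake, roi)
}
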