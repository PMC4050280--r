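#' Vesicle model
#'
#' A sphere standing in for the segmented vesicle membrane.
#'
#' @param centre length-3 Angstrom position of the sphere centre.
#' @param radius sphere radius in Angstrom, > 0.
#' @return an object of class `vesicle_model`.
#' @export
vesicle_model <- function(centre, radius) {
  if (length(centre) != 3 || any(!is.finite(centre)))
    abort("`centre` must be a finite length-3 vector")
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    abort("`radius` must be a single positive number")
  structure(list(centre = as.numeric(centre), radius = as.numeric(radius)),
            class = "vesicle_model")
}

#' @export
print.vesicle_model <- function(x, ...) {
  cat(sprintf("<vesicle_model> centre (%g, %g, %g) A, radius %g A\n",
              x$centre[1], x$centre[2], x$centre[3], x$radius))
  invisible(x)
}

as_vesicle_list <- function(vesicles) {
  if (inherits(vesicles, "vesicle_model")) return(list(vesicles))
  if (!is.list(vesicles) || !length(vesicles) ||
      !all(vapply(vesicles, inherits, logical(1), "vesicle_model")))
    abort("`vesicles` must be a vesicle_model or a non-empty list of them")
  vesicles
}

#' Distance of points to vesicle membranes
#'
#' Unsigned radial distance `| ||p - centre|| - radius |` to each vesicle;
#' returns the per-point minimum over vesicles and the index of the nearest
#' vesicle.
#'
#' @param pos n x 3 matrix of Angstrom positions.
#' @param vesicles a `vesicle_model` or list of them.
#' @return tibble with columns `dist` (Angstrom) and `vesicle` (index).
#' @export
membrane_distance <- function(pos, vesicles) {
  pos <- rbind_pos(pos)
  vesicles <- as_vesicle_list(vesicles)
  dmat <- vapply(vesicles, function(v) {
    abs(sqrt(rowSums(sweep(pos, 2, v$centre)^2)) - v$radius)
  }, numeric(nrow(pos)))
  dmat <- matrix(dmat, nrow = nrow(pos))
  idx <- max.col(-dmat, ties.method = "first")
  tibble(dist = dmat[cbind(seq_len(nrow(pos)), idx)], vesicle = idx)
}

#' Fit a sphere to membrane samples
#'
#' Least-squares sphere fit: the algebraic (Coope) linear fit followed by
#' Gauss-Newton geometric refinement. In map mode the input samples are the
#' dark-shell voxels of the map (values below `mean - 2 SD`), iteratively
#' trimmed to the dominant radial band so that decorating protein density
#' does not drag the radius outward.
#'
#' @param x either an n x 3 matrix of surface points (Angstrom, n >= 4,
#'   non-coplanar) or a [density_map()] with shell contrast.
#' @return a [vesicle_model()].
#' @export
fit_vesicle_sphere <- function(x) {
  if (is_density_map(x)) {
    g <- x$grid
    thr <- mean(g) - 2 * sd(g)
    idx <- which(g < thr)
    if (length(idx) < 50) abort("sphere fit error: too few dark voxels in map")
    ijk <- arrayInd(idx, dim(g)) - 1L
    pts <- voxel_to_map(x, ijk)
    fit <- fit_sphere_points(pts)
    # robust trim: keep samples in the dominant radial band, refit
    for (rep in 1:3) {
      r <- sqrt(rowSums(sweep(pts, 2, fit$centre)^2))
      keep <- abs(r - fit$radius) < pmax(30, 0.08 * fit$radius)
      if (sum(keep) < 50) break
      fit <- fit_sphere_points(pts[keep, , drop = FALSE])
    }
    return(vesicle_model(fit$centre, fit$radius))
  }
  pts <- rbind_pos(x)
  fit <- fit_sphere_points(pts)
  vesicle_model(fit$centre, fit$radius)
}

fit_sphere_points <- function(pts) {
  n <- nrow(pts)
  if (n < 4) abort("sphere fit error: need at least 4 points")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qr_ <- qr(A)
  if (qr_$rank < 4) abort("sphere fit error: points are coplanar or degenerate")
  sol <- qr.coef(qr_, b)
  centre <- sol[1:3]
  r2 <- sol[4] + sum(centre^2)
  if (!is.finite(r2) || r2 <= 0) abort("sphere fit error: degenerate radius")
  radius <- sqrt(r2)
  # Gauss-Newton on (centre, radius) minimizing sum (||p-c|| - r)^2
  for (it in 1:20) {
    d <- sweep(pts, 2, centre)
    r <- sqrt(rowSums(d^2))
    r[r < 1e-9] <- 1e-9
    res <- r - radius
    J <- cbind(-d / r, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    centre <- centre - step[1:3]
    radius <- radius - step[4]
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  list(centre = as.numeric(centre), radius = as.numeric(radius))
}

#' Tilt-series geometry
#'
#' Data-collection geometry of the tilt series: angular range, increment
#' and the in-plane tilt axis. Used by [apply_missing_wedge()].
#'
#' @param tilt_min,tilt_max angular range in degrees, `tilt_min < tilt_max`.
#' @param increment tilt increment in degrees (> 0; recorded for
#'   provenance, the wedge mask depends only on the range).
#' @param tilt_axis `"x"` or `"y"`, the in-plane axis about which the
#'   specimen is tilted.
#' @return an object of class `tilt_geometry`.
#' @export
#' @examples
#' tilt_geometry(-60, 60, increment = 3)
tilt_geometry <- function(tilt_min = -60, tilt_max = 60, increment = 3,
                          tilt_axis = c("y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(tilt_min) || !is.finite(tilt_max) || tilt_min >= tilt_max)
    abort("`tilt_min` must be smaller than `tilt_max`")
  if (!is.finite(increment) || increment <= 0)
    abort("`increment` must be positive")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 increment = increment, tilt_axis = tilt_axis),
            class = "tilt_geometry")
}
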