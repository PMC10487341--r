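#' Fit the network's mid-plane by least squares
#'
#' The chip's gel channel should be horizontal, but small chip/microscope
#' misalignment tilts the imaged network. The plane z = alpha x + beta y
#' + gamma is fitted (ordinary least squares) to one point per occupied
#' (x, y) column: the mean z of the foreground voxels in that column.
#' Per-column averaging makes the fit insensitive to vessel thickness.
#'
#' @param mask a nonempty [binary_mask()].
#' @return A list with `alpha`, `beta`, `gamma` (micrometre units),
#'   `normal` (unit 3-vector, positive z) and `offset` such that points
#'   on the plane satisfy `sum(normal * p) == offset`.
#' @export
fit_plane <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  sp <- mask$spacing
  col_id <- idx[, 1] + (idx[, 2] - 1) * dim(mask$data)[1]
  zsum <- rowsum(as.numeric(idx[, 3]), col_id)
  cnt <- rowsum(rep(1, nrow(idx)), col_id)
  cid <- as.integer(rownames(zsum))
  nxd <- dim(mask$data)[1]
  x <- ((cid - 1) %% nxd) * sp[1]
  y <- ((cid - 1) %/% nxd) * sp[2]
  z <- (zsum[, 1] / cnt[, 1] - 1) * sp[3]
  if (length(x) < 3) stop("fewer than 3 occupied columns; cannot fit a plane")
  X <- cbind(1, x, y)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("occupied columns are collinear; cannot fit a plane")
  beta_hat <- solve(XtX, crossprod(X, z))
  alpha <- beta_hat[2]; beta <- beta_hat[3]; gamma <- beta_hat[1]
  n <- c(-alpha, -beta, 1)
  n <- n / sqrt(sum(n^2))
  list(alpha = alpha, beta = beta, gamma = gamma,
       normal = n, offset = n[3] * gamma)
}

# Rotation matrix taking unit vector 'a' onto unit vector 'b' (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Rotate the network so its mid-plane is horizontal
#'
#' Applies the rigid rotation taking the fitted plane normal to (0,0,1),
#' about the volume center, and resamples the mask with nearest-neighbor
#' lookup (preserving binarity). Rigid rotation (rather than a z-shear)
#' preserves branch lengths exactly. Voxels rotated out of the volume are
#' dropped; their count is reported as an attribute.
#'
#' @param mask a [binary_mask()].
#' @param max_tilt_deg tilt angles below this threshold (default 0.05
#'   degrees) are treated as already level and the mask is returned
#'   unchanged.
#' @return The aligned [binary_mask()], with attributes `tilt_deg`
#'   (the removed tilt) and `dropped` (out-of-bounds voxel count).
#' @export
align_vertical <- function(mask, max_tilt_deg = 0.05) {
  stopifnot(inherits(mask, "binary_mask"))
  pl <- fit_plane(mask)
  tilt <- acos(min(1, pl$normal[3])) * 180 / pi
  if (tilt < max_tilt_deg) {
    attr(mask, "tilt_deg") <- tilt
    attr(mask, "dropped") <- 0L
    return(mask)
  }
  R <- rotation_between(pl$normal, c(0, 0, 1))
  d <- dim(mask$data)
  sp <- mask$spacing
  ctr <- (d - 1) / 2 * sp
  # inverse mapping: for each output voxel center, sample the input
  out_idx <- which(array(TRUE, d), arr.ind = TRUE)
  p <- sweep(voxel_coords(out_idx, sp), 2, ctr, "-")
  src <- p %*% R + matrix(ctr, nrow(p), 3, byrow = TRUE)  # R^-1 = t(R); p %*% R == t(t(R) %*% t(p))
  si <- round(sweep(src, 2, sp, "/")) + 1
  ok <- si[, 1] >= 1 & si[, 1] <= d[1] &
        si[, 2] >= 1 & si[, 2] <= d[2] &
        si[, 3] >= 1 & si[, 3] <= d[3]
  vals <- logical(nrow(si))
  vals[ok] <- mask$data[si[ok, , drop = FALSE]]
  out <- binary_mask(array(vals, d), sp, mask$origin)
  attr(out, "tilt_deg") <- tilt
  attr(out, "dropped") <- sum(mask$data) - sum(vals)
  out
}
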