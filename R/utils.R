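# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report tables round percent changes with halves away from zero (base
#' `round()` rounds half to even, which would print 54.25 as 54.2).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Rotation matrix R = Rz(rz) %*% Ry(ry) %*% Rx(rx), angles in degrees.
# Mirrors the convention of the compiled resampler.
rotation_matrix <- function(rot_deg) {
  a <- rot_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  matrix(c(
    cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
    sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
    -sy,     cy * sx,                cy * cx), 3, 3, byrow = TRUE)
}

# Euler angles (degrees, Rz Ry Rx convention) of a rotation matrix.
euler_angles <- function(R) {
  ry <- -asin(max(-1, min(1, R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz) * 180 / pi
}

# Invert a rigid transform given as (rotation degrees, translation mm)
# acting as x -> R (x - c) + c + t about a fixed centre c.
invert_rigid <- function(rot_deg, trans_mm) {
  R <- rotation_matrix(rot_deg)
  list(rot_deg = euler_angles(t(R)), trans_mm = as.numeric(-t(R) %*% trans_mm))
}

#' Per-stage RNG seed derived from a master seed
#'
#' Hashes the stage name into the master seed so every stochastic stage of a
#' study gets its own reproducible stream and can be rerun independently.
#' Always below 2^31 (a valid R integer).
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 10007) %% 2147483647)
}

# Spherical <-> Cartesian for unit orientations (polar theta from +z).
sph_to_cart <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}
cart_to_sph <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  cbind(theta = acos(pmax(-1, pmin(1, v[, 3]))), phi = atan2(v[, 2], v[, 1]))
}

# Angle in degrees between two unit vectors, ignoring sign (fiber
# orientations are axial).
axial_angle <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
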