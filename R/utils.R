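# internal geometry / numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Wrap an angle in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps exactly -180 to -180; convention is (-180, 180]
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# atomic masses (Da); unknown elements get unit mass (coarse-grained beads)
.ATOMIC_MASS <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "S" = 32.06,
  "P" = 30.974, "F" = 18.998, "CL" = 35.45, "BR" = 79.904, "I" = 126.904,
  "FE" = 55.845, "ZN" = 65.38, "MG" = 24.305, "NA" = 22.99, "K" = 39.098
)

element_mass <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- 1
  unname(m)
}

# rotation matrix for angle (degrees) about unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# random proper rotation matrix (uniform via QR of gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply rigid transform to an n x 3 coordinate matrix
apply_rigid <- function(coords, R = diag(3), t = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2, t, `+`)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
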