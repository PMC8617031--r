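# Low-level 3D geometry used across the package. All coordinates in angstrom,
# all angles in degrees unless a name says otherwise.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-10) stop("cannot normalise a (near-)zero-length vector")
  a / n
}

#' Signed torsion angle of four points
#'
#' Returns the dihedral p1-p2-p3-p4 under the IUPAC sign convention, reported
#' on the half-open interval `[-180, 180)` so that a trans arrangement is
#' `-180`, never `+180`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees in `[-180, 180)`.
#' @keywords internal
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * .rad2deg
  wrap_angle(ang)
}

# wrap any angle in degrees onto [-180, 180)
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a >= 180] <- a[a >= 180] - 360
  a
}

#' Rotation matrix about a unit axis (Rodrigues formula)
#' @param u unit 3-vector axis.
#' @param theta angle in degrees, right-hand rule about `u`.
#' @keywords internal
rodrigues <- function(u, theta) {
  th <- theta * .deg2rad
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# rigid transform (R, t) for rotation by theta about the axis through `point`
# with direction `u`; x -> R (x - point) + point
axis_rotation <- function(point, u, theta) {
  R <- rodrigues(u, theta)
  list(R = R, t = as.numeric(point - R %*% point))
}

# apply list(R, t) transform to an n x 3 coordinate matrix
apply_rt <- function(xyz, rt) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(rt$R), 2, -rt$t)
}

# compose: apply `first`, then `second`
compose_rt <- function(second, first) {
  list(R = second$R %*% first$R,
       t = as.numeric(second$R %*% first$t) + second$t)
}

invert_rt <- function(rt) {
  Rt <- t(rt$R)
  list(R = Rt, t = as.numeric(-Rt %*% rt$t))
}

identity_rt <- function() list(R = diag(3), t = c(0, 0, 0))

# rotation taking direction a onto direction b (minimal rotation)
align_vectors <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- vcross(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rodrigues(unitv(vcross(a, ref)), 180))
  }
  rodrigues(v / s, atan2(s, c_) * .rad2deg)
}

#' Place an atom from internal coordinates (NERF construction)
#'
#' Given three existing positions a-b-c, returns the position `d` with
#' `|c-d| = bond`, angle b-c-d equal to `angle`, and torsion a-b-c-d equal to
#' `torsion`.
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * .deg2rad
  tor <- -torsion * .deg2rad  # sign fixed against torsion_angle()'s convention
  u2 <- unitv(c - b)
  n <- unitv(vcross(b - a, u2))
  m <- vcross(n, u2)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d_local[1] * u2 + d_local[2] * m + d_local[3] * n
}

# near-uniform points on the unit sphere (generalised spiral), deterministic
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Euclidean distance between two 3-vectors
dist3 <- function(a, b) sqrt(sum((a - b)^2))

`%||%` <- function(x, y) if (is.null(x)) y else x

# run code with a private, seed-controlled RNG stream, restoring the caller's
# RNG state afterwards
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
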