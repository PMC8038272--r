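# SO(3) utilities used throughout the package.
#
# Conventions: rotation matrices are 3x3, act on column vectors, and map
# sensor-frame vectors into the global frame (v_global = R %*% v_sensor).
# Time series of rotations are stored as 3 x 3 x N arrays.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Elementary rotations about the coordinate axes
#'
#' Right-handed rotations about the x, y and z axes. In the anatomical frame
#' used by this package x is the medio-lateral axis (flexion-extension),
#' y the antero-posterior axis (lateral bending) and z the longitudinal axis
#' (axial twist).
#'
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  rbind(c(1, 0, 0),
        c(0, cos(a), -sin(a)),
        c(0, sin(a), cos(a)))
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  rbind(c(cos(a), 0, sin(a)),
        c(0, 1, 0),
        c(-sin(a), 0, cos(a)))
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  rbind(c(cos(a), -sin(a), 0),
        c(sin(a), cos(a), 0),
        c(0, 0, 1))
}

#' Project a matrix onto the rotation group
#'
#' Returns the rotation matrix nearest to `M` in Frobenius norm (the
#' orthogonal polar factor, computed by singular value decomposition). Used
#' to repair serialization rounding in orientation samples and to compute
#' chordal means.
#'
#' @param M a 3x3 real matrix with positive determinant.
#' @return The nearest 3x3 rotation matrix (orthonormal to ~1e-12,
#'   determinant +1).
#' @export
orthonormalize <- function(M) {
  if (!is.matrix(M) || !identical(dim(M), c(3L, 3L)) || !all(is.finite(M))) {
    stop("orthonormalize() expects a finite 3x3 matrix")
  }
  if (det(M) <= 0) {
    stop("matrix has non-positive determinant: not repairable to a rotation")
  }
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    # cannot occur for det(M) > 0, but guard against degenerate SVD signs
    R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  R
}

# Frobenius-norm orthogonality defect ||R'R - I||_F per slice of a 3x3xN array.
orthogonality_defect <- function(Rarr) {
  G <- rot_array_crossprod(Rarr, Rarr)
  G[1, 1, ] <- G[1, 1, ] - 1
  G[2, 2, ] <- G[2, 2, ] - 1
  G[3, 3, ] <- G[3, 3, ] - 1
  sqrt(apply(G^2, 3, sum))
}

# Determinant per slice of a 3x3xN array (vectorized cofactor expansion).
rot_array_det <- function(Rarr) {
  Rarr[1, 1, ] * (Rarr[2, 2, ] * Rarr[3, 3, ] - Rarr[2, 3, ] * Rarr[3, 2, ]) -
    Rarr[1, 2, ] * (Rarr[2, 1, ] * Rarr[3, 3, ] - Rarr[2, 3, ] * Rarr[3, 1, ]) +
    Rarr[1, 3, ] * (Rarr[2, 1, ] * Rarr[3, 2, ] - Rarr[2, 2, ] * Rarr[3, 1, ])
}

# C[,,k] = A[,,k] %*% B[,,k]; either argument may be a single 3x3 matrix,
# which is recycled across slices.
rot_array_mult <- function(A, B) {
  if (is.matrix(A) && is.matrix(B)) return(A %*% B)
  n <- if (is.matrix(A)) dim(B)[3] else dim(A)[3]
  a <- function(i, k) if (is.matrix(A)) A[i, k] else A[i, k, ]
  b <- function(k, j) if (is.matrix(B)) B[k, j] else B[k, j, ]
  C <- array(0, c(3, 3, n))
  for (i in 1:3) for (j in 1:3) {
    C[i, j, ] <- a(i, 1) * b(1, j) + a(i, 2) * b(2, j) + a(i, 3) * b(3, j)
  }
  C
}

# C[,,k] = t(A[,,k]) %*% B[,,k]
rot_array_crossprod <- function(A, B) {
  n <- if (is.matrix(A)) dim(B)[3] else dim(A)[3]
  a <- function(k, i) if (is.matrix(A)) A[k, i] else A[k, i, ]
  b <- function(k, j) if (is.matrix(B)) B[k, j] else B[k, j, ]
  C <- array(0, c(3, 3, n))
  for (i in 1:3) for (j in 1:3) {
    C[i, j, ] <- a(1, i) * b(1, j) + a(2, i) * b(2, j) + a(3, i) * b(3, j)
  }
  C
}

#' Geodesic distance between rotations
#'
#' The rotation angle, in degrees, of \eqn{R_1^{-1} R_2} — the natural
#' (geodesic) distance on SO(3).
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle in degrees in [0, 180].
#' @export
geodesic_angle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(min(1, max(-1, (tr - 1) / 2))) * RAD2DEG
}

#' Chordal (L2) mean of a set of rotations
#'
#' Element-wise mean of the rotation matrices projected back onto the
#' rotation group. Unique and well behaved for tightly clustered samples,
#' which is the regime of a static calibration pose.
#'
#' @param Rarr a 3x3xN array of rotation matrices.
#' @return A 3x3 rotation matrix.
#' @export
chordal_mean_rotation <- function(Rarr) {
  stopifnot(length(dim(Rarr)) == 3, dim(Rarr)[1] == 3, dim(Rarr)[2] == 3)
  M <- apply(Rarr, c(1, 2), mean)
  orthonormalize(M)
}

#' Convert unit quaternions to rotation matrices
#'
#' Scalar-first (w, x, y, z) convention. Quaternions are normalized before
#' conversion; inputs far from unit norm are a data error handled by the
#' readers.
#'
#' @param q an N x 4 matrix of quaternions, columns (w, x, y, z).
#' @return A 3x3xN array of rotation matrices.
#' @export
quat_to_rotmat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 4)
  nrm <- sqrt(rowSums(q^2))
  q <- q / nrm
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- array(0, c(3, 3, nrow(q)))
  R[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  R[1, 2, ] <- 2 * (x * y - w * z)
  R[1, 3, ] <- 2 * (x * z + w * y)
  R[2, 1, ] <- 2 * (x * y + w * z)
  R[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  R[2, 3, ] <- 2 * (y * z - w * x)
  R[3, 1, ] <- 2 * (x * z - w * y)
  R[3, 2, ] <- 2 * (y * z + w * x)
  R[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  R
}

# Rodrigues formula, vectorized: axes as 3xN (normalized internally),
# angles in radians, length N. Returns 3x3xN.
axis_angle_rotmat <- function(axis, angle_rad) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 3)
  n <- length(angle_rad)
  nrm <- sqrt(colSums(axis^2))
  nrm[nrm == 0] <- 1
  u <- sweep(axis, 2, nrm, "/")
  ca <- cos(angle_rad); sa <- sin(angle_rad); vc <- 1 - ca
  ux <- u[1, ]; uy <- u[2, ]; uz <- u[3, ]
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- ca + ux^2 * vc
  R[1, 2, ] <- ux * uy * vc - uz * sa
  R[1, 3, ] <- ux * uz * vc + uy * sa
  R[2, 1, ] <- uy * ux * vc + uz * sa
  R[2, 2, ] <- ca + uy^2 * vc
  R[2, 3, ] <- uy * uz * vc - ux * sa
  R[3, 1, ] <- uz * ux * vc - uy * sa
  R[3, 2, ] <- uz * uy * vc + ux * sa
  R[3, 3, ] <- ca + uz^2 * vc
  R
}

#' Compose segment angles into a rotation
#'
#' Builds the segment rotation from flexion, lateral bending and twist using
#' the package's declared intrinsic sequence: flexion about the medio-lateral
#' axis (x), then lateral bending about the antero-posterior axis (y), then
#' axial twist about the longitudinal axis (z), i.e.
#' \eqn{R = R_x(f)\,R_y(b)\,R_z(t)}. Flexion is kept first in the sequence so
#' that the dominant risk driver (flexo-extension) is the least distorted
#' angle.
#'
#' @param flexion,bending,twist angle vectors in degrees (equal length).
#' @return A 3x3xN array of rotation matrices.
#' @seealso [euler_decompose()] for the inverse.
#' @export
euler_compose <- function(flexion, bending, twist) {
  stopifnot(length(flexion) == length(bending),
            length(flexion) == length(twist))
  a <- flexion * DEG2RAD; b <- bending * DEG2RAD; c <- twist * DEG2RAD
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  R <- array(0, c(3, 3, length(a)))
  R[1, 1, ] <- cb * cc
  R[1, 2, ] <- -cb * sc
  R[1, 3, ] <- sb
  R[2, 1, ] <- ca * sc + sa * sb * cc
  R[2, 2, ] <- ca * cc - sa * sb * sc
  R[2, 3, ] <- -sa * cb
  R[3, 1, ] <- sa * sc - ca * sb * cc
  R[3, 2, ] <- sa * cc + ca * sb * sc
  R[3, 3, ] <- ca * cb
  R
}

#' Decompose a segment rotation into anatomical angles
#'
#' Inverse of [euler_compose()]: recovers (flexion, bending, twist) in
#' degrees from a rotation (or a 3x3xN array of rotations). All outputs lie
#' in (-180, 180]. Near gimbal lock (|bending| within 0.5 degrees of 90) the
#' flexion/twist split is ill-conditioned; affected samples are flagged with
#' a warning and returned using the conventional twist = 0 resolution.
#'
#' @param R a 3x3 rotation matrix or 3x3xN array.
#' @return A data.frame with columns `flexion_deg`, `bending_deg`,
#'   `twist_deg` and logical `gimbal`.
#' @export
euler_decompose <- function(R) {
  if (is.matrix(R)) R <- array(R, c(3, 3, 1))
  r13 <- pmin(1, pmax(-1, R[1, 3, ]))
  bending <- asin(r13)
  flexion <- atan2(-R[2, 3, ], R[3, 3, ])
  twist <- atan2(-R[1, 2, ], R[1, 1, ])
  gimbal <- abs(abs(bending) - pi / 2) < 0.5 * DEG2RAD
  if (any(gimbal)) {
    # r11,r12,r23,r33 all ~0: only flexion +/- twist is observable
    flexion[gimbal] <- atan2(R[2, 1, gimbal], R[2, 2, gimbal])
    twist[gimbal] <- 0
    warning(sum(gimbal), " sample(s) in the gimbal-lock band (|bending| ~ 90 deg); ",
            "twist set to 0 there")
  }
  data.frame(flexion_deg = flexion * RAD2DEG,
             bending_deg = bending * RAD2DEG,
             twist_deg = twist * RAD2DEG,
             gimbal = gimbal)
}
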