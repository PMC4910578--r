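#' @keywords internal
"_PACKAGE"

## Residue keys are "chain:resno:ins" strings; insertion code is "" when absent.
res_key <- function(chain, resno, ins = "") {
  ins[is.na(ins)] <- ""
  paste(chain, resno, ins, sep = ":")
}

split_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    ins   = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

## Standard three- to one-letter amino acid mapping (X for anything else).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

aa321 <- function(resid) {
  out <- AA3TO1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

AA1TO3 <- setNames(names(AA3TO1)[1:20], unname(AA3TO1[1:20]))

## Residue classes used by the strand-8' motif validator and the
## principal-side heuristics.
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")
SMALL_AA <- c("G", "A", "S")

#' Rigid-body transform
#'
#' Bundles a rotation and translation acting as
#' `x %*% t(R) + t` on row-vector coordinates.
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector, Angstrom.
#' @return A list with components `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)), length(t) == 3L)
  list(R = R, t = as.numeric(t))
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param tr A transform from [rigid_transform()].
#' @return The transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tr) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tr$R), 2L, tr$t, `+`)
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula for a rotation by `theta` radians about `axis`.
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param theta Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Random proper rotation from a seeded stream (QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## Quaternion helpers for the swing-twist decomposition used by
## domain_motion(): rotation matrix -> unit quaternion (w, x, y, z).
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

## Decompose a rotation into twist about `axis` plus a residual swing.
## Returns angles in degrees, both in [0, 180].
swing_twist <- function(R, axis) {
  q <- rotmat_to_quat(R)
  n <- axis / sqrt(sum(axis^2))
  v <- q[2:4]
  proj <- sum(v * n) * n
  tw <- c(q[1], proj)
  nrm <- sqrt(sum(tw^2))
  if (nrm < 1e-12) {
    ## 180-degree swing exactly orthogonal to the axis
    twist <- 0
  } else {
    tw <- tw / nrm
    twist <- 2 * atan2(sqrt(sum(tw[2:4]^2)), abs(tw[1])) * 180 / pi
  }
  total <- 2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
  ## swing = residual after removing the twist component
  Rt <- rotation_about_axis(n, sign(sum(v * n)) * twist * pi / 180)
  Rs <- R %*% t(Rt)
  qs <- rotmat_to_quat(Rs)
  swing <- 2 * atan2(sqrt(sum(qs[2:4]^2)), abs(qs[1])) * 180 / pi
  list(twist = twist, swing = swing, total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
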