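#' Canonical frontal 68-point face template
#'
#' A synthetic 3-D face template in iBUG-68 ordering (17 jaw, 10 brow,
#' 9 nose, 12 eye, 20 lip points), bilaterally symmetric about the x = 0
#' plane, centered at its centroid, in arbitrary units. The +x axis points
#' toward the subject's left, +y up, +z out of the face toward the camera.
#' Any template satisfying these conventions can be substituted (see
#' [readFaceTemplate()]); pose recovery only uses relative geometry.
#'
#' @return A 68 x 3 numeric matrix.
#' @export
canonicalFaceTemplate <- function() {
  pts <- matrix(NA_real_, 68, 3)
  # jaw 1-17: arc from the subject's right to left
  th <- pi * (0:16) / 16
  pts[1:17, ] <- cbind(-80 * cos(th), 20 - 120 * sin(th),
                       -20 - 25 * sin(th))
  # brows 18-27
  arch <- c(0, 5, 8, 5, 0)
  pts[18:22, ] <- cbind(seq(-60, -15, length.out = 5), 45 + arch, 12)
  pts[23:27, ] <- cbind(seq(15, 60, length.out = 5), 45 + arch, 12)
  # nose bridge 28-31 (31 = tip) and base 32-36
  pts[28:31, ] <- cbind(0, seq(35, 5, length.out = 4), seq(20, 50, length.out = 4))
  pts[32:36, ] <- cbind(c(-18, -9, 0, 9, 18), -5, c(30, 38, 42, 38, 30))
  # eyes 37-42 (subject's right / viewer's left), 43-48 mirrored
  eye <- cbind(c(-45, -40, -30, -25, -30, -40),
               c(25, 29, 29, 25, 21, 21),
               c(15, 18, 18, 15, 18, 18))
  pts[37:42, ] <- eye
  pts[43:48, ] <- cbind(-eye[c(4, 3, 2, 1, 6, 5), 1], eye[c(4, 3, 2, 1, 6, 5), 2],
                        eye[c(4, 3, 2, 1, 6, 5), 3])
  # outer lip 49-60, inner lip 61-68
  a12 <- pi / 180 * seq(180, -150, by = -30)
  pts[49:60, ] <- cbind(30 * cos(a12), -55 + 12 * sin(a12), 25)
  a8 <- pi / 180 * seq(180, -135, by = -45)
  pts[61:68, ] <- cbind(18 * cos(a8), -55 + 6 * sin(a8), 27)
  sweep(pts, 2, colMeans(pts))
}

#' Default rigid landmark subset for pose recovery
#'
#' Jaw extremes (1, 17), top of the nose bridge (28), nose tip (31) and the
#' four eye corners (37, 40, 43, 46): points that move little with facial
#' expression, in 1-based iBUG-68 indexing.
#'
#' @return Integer vector of landmark indices.
#' @export
defaultRigidIndices <- function() c(1L, 17L, 28L, 31L, 37L, 40L, 43L, 46L)

#' Read a face template from a plain-text file
#'
#' @param path text file with 68 rows and 3 whitespace-separated columns.
#' @return A 68 x 3 matrix centered at its centroid.
#' @export
readFaceTemplate <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != 68L || ncol(m) != 3L)
    stop("face template must be 68 rows x 3 columns, got ",
         nrow(m), " x ", ncol(m))
  dimnames(m) <- NULL
  sweep(m, 2, colMeans(m))
}

#' Intrinsic rotation matrix from yaw, pitch, roll (degrees)
#'
#' Composition `Ry(yaw) %*% Rx(pitch) %*% Rz(roll)`. Positive yaw rotates
#' the face toward the subject's left (+x).
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(yaw, pitch = 0, roll = 0) {
  a <- yaw * pi / 180; b <- pitch * pi / 180; g <- roll * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

#' Project a rotated 3-D template to 2-D landmarks
#'
#' Weak-perspective (scaled orthographic) camera: rotate, drop z, scale and
#' translate. Used as the forward model in tests and by the simulator when
#' landmark streams are requested.
#'
#' @param points3d n x 3 matrix.
#' @param yaw,pitch,roll pose angles in degrees.
#' @param scale uniform image scale.
#' @param translation length-2 image offset.
#' @return n x 2 matrix of image coordinates (x right, y up).
#' @export
projectLandmarks <- function(points3d, yaw = 0, pitch = 0, roll = 0,
                             scale = 1, translation = c(0, 0)) {
  R <- rotationMatrix(yaw, pitch, roll)
  p <- points3d %*% t(R)
  sweep(p[, 1:2, drop = FALSE] * scale, 2, -translation)
}

#' Estimate head pose from 68 2-D landmarks
#'
#' Fits a weak-perspective rigid alignment of the template's rigid subset
#' to the observed landmarks: a least-squares 2 x 3 affine map followed by
#' projection (via SVD) onto the nearest scaled rotation, from which yaw,
#' pitch and roll are extracted. No camera intrinsics are required.
#'
#' @param landmarks 68 x 2 matrix (x right, y up), iBUG-68 order.
#' @param template 68 x 3 frontal template (default
#'   [canonicalFaceTemplate()]).
#' @param rigidIndices landmark subset used for the fit.
#' @return List with `yaw`, `pitch`, `roll` in degrees; yaw lies in
#'   `[-90, 90]` for physically plausible head turns, positive when the
#'   face turns toward its own left.
#' @export
estimatePose <- function(landmarks, template = canonicalFaceTemplate(),
                         rigidIndices = defaultRigidIndices()) {
  if (!is.matrix(landmarks) || nrow(landmarks) != 68L || ncol(landmarks) != 2L)
    stop("landmarks must be a 68 x 2 matrix")
  if (!all(is.finite(landmarks)))
    stop("landmarks must be finite")
  est <- .poseCore(landmarks, template, rigidIndices)
  if (abs(est$yaw) > 90) {
    # A |yaw| > 90 (back-of-head) fit is the improper twin of a frontal
    # pose: by bilateral template symmetry, x-mirrored landmarks admit an
    # equivalent frontal explanation with negated yaw and roll.
    mirrored <- cbind(-landmarks[, 1], landmarks[, 2])
    alt <- .poseCore(mirrored, template, rigidIndices)
    est <- list(yaw = -alt$yaw, pitch = alt$pitch, roll = -alt$roll)
  }
  est
}

.poseCore <- function(landmarks, template, rigidIndices) {
  L <- landmarks[rigidIndices, , drop = FALSE]
  X <- template[rigidIndices, , drop = FALSE]
  Lc <- sweep(L, 2, colMeans(L))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Lc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-300))
    stop("degenerate landmarks: points are (nearly) collinear")
  # Lc ~ Xc %*% t(M), M = s * first two rows of R
  M <- t(solve(crossprod(Xc), crossprod(Xc, Lc)))
  dec <- svd(M)
  R12 <- dec$u %*% t(dec$v)
  r3 <- c(R12[1, 2] * R12[2, 3] - R12[1, 3] * R12[2, 2],
          R12[1, 3] * R12[2, 1] - R12[1, 1] * R12[2, 3],
          R12[1, 1] * R12[2, 2] - R12[1, 2] * R12[2, 1])
  R <- rbind(R12, r3)
  clamp <- function(x) max(-1, min(1, x))
  list(yaw = unname(atan2(R[1, 3], R[3, 3])) * 180 / pi,
       pitch = unname(asin(clamp(-R[2, 3]))) * 180 / pi,
       roll = unname(atan2(R[2, 1], R[2, 2])) * 180 / pi)
}

#' Estimate head yaw (degrees) from 68 landmarks
#'
#' @inheritParams estimatePose
#' @return Yaw angle in degrees.
#' @export
estimateYaw <- function(landmarks, template = canonicalFaceTemplate(),
                        rigidIndices = defaultRigidIndices()) {
  estimatePose(landmarks, template, rigidIndices)$yaw
}

#' Is the head facing the caller?
#'
#' @param yaw head yaw in degrees.
#' @param threshold facing threshold in degrees (> 0); boundary inclusive.
#' @return Logical; `TRUE` iff `|yaw| <= threshold`.
#' @export
isFacing <- function(yaw, threshold = 30) {
  stopifnot(threshold > 0)
  abs(yaw) <= threshold
}

#' Fill per-frame yaw from landmarks
#'
#' Returns the segment with `yaw_deg` computed from landmarks wherever it
#' is missing; frames that carry neither landmarks nor yaw are left
#' unannotated (downstream they default to "facing" — a detected face with
#' no pose information is not assumed to be averted). Idempotent.
#'
#' @param segment a [ProcedureSegment-class].
#' @param template face template for [estimateYaw()].
#' @param rigidIndices landmark subset for the fit.
#' @return The annotated [ProcedureSegment-class].
#' @export
annotateFrames <- function(segment, template = canonicalFaceTemplate(),
                           rigidIndices = defaultRigidIndices()) {
  fr <- segment@frames
  if (!nrow(fr)) return(segment)
  for (i in seq_len(nrow(fr))) {
    if (is.na(fr$yaw_deg[i]) && !is.null(fr$landmarks[[i]]))
      fr$yaw_deg[i] <- estimateYaw(fr$landmarks[[i]], template, rigidIndices)
  }
  segment@frames <- fr
  segment
}
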