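## Superposition, RMSD and distance machinery plus the ideal B-form
## reference strand whose adjacent phosphate spacing serves as the
## one-nucleotide translocation yardstick.

.newSeries <- function(time_ns, value) {
  data.frame(time_ns = as.numeric(time_ns), value = as.numeric(value))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of the
#' fit atoms between a mobile and a reference frame, and applies it to
#' every atom of the mobile frame. The reflection branch of the SVD is
#' never chosen.
#'
#' @param mobile n x 3 coordinate matrix (Angstrom)
#' @param reference n x 3 coordinate matrix on the same atom order
#' @param fitAtoms integer atom positions used for the fit (>= 3,
#'   non-collinear)
#' @return list(transform = RigidTransform, coords = fitted mobile
#'   coords, fitRmsd = RMSD over the fit atoms after superposition)
#' @export
kabschSuperpose <- function(mobile, reference, fitAtoms) {
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  if (length(fitAtoms) < 3L)
    stop("at least 3 fit atoms are required")
  P <- mobile[fitAtoms, , drop = FALSE]
  Q <- reference[fitAtoms, , drop = FALSE]
  if (anyNA(P) || anyNA(Q)) stop("NA coordinates in fit set")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))  # H = P^T Q
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit atom set: superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(mobile %*% t(R), 2, tr, "+")
  fitRmsd <- sqrt(mean(rowSums((fitted[fitAtoms, , drop = FALSE] - Q)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = tr),
       coords = fitted, fitRmsd = fitRmsd)
}

#' Apply a rigid transform to coordinates
#' @param transform a RigidTransform
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(transform, coords) {
  sweep(coords %*% t(transform@rotation), 2, transform@translation, "+")
}

#' Time series of superposed RMSD (or single-atom displacement)
#'
#' Per frame: superpose on the fit atoms, then RMSD over the measure
#' atoms against the reference. A single-atom measure set yields the
#' plain displacement distance of that atom from its reference
#' position.
#'
#' @param traj a Trajectory
#' @param reference n x 3 reference frame on the same atom order
#' @param fitAtoms integer fit atom positions
#' @param measureAtoms integer measure atom positions
#' @return data.frame(time_ns, value) in Angstrom
#' @export
rmsdSeries <- function(traj, reference, fitAtoms, measureAtoms) {
  if (!length(measureAtoms)) stop("empty measure selection")
  refM <- reference[measureAtoms, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    fit <- kabschSuperpose(frameCoords(traj, f), reference, fitAtoms)
    m <- fit$coords[measureAtoms, , drop = FALSE]
    sqrt(mean(rowSums((m - refM)^2)))
  }, numeric(1))
  .newSeries(trajTimes(traj), vals)
}

#' Distance time series between two atom groups
#'
#' @param traj a Trajectory
#' @param groupA,groupB integer atom positions
#' @param mode "ca_pair" (exactly one atom per group), "min_heavy"
#'   (minimum over all cross pairs) or "centroid" (distance of
#'   unweighted centroids)
#' @return data.frame(time_ns, value) in Angstrom
#' @export
distanceSeries <- function(traj, groupA, groupB,
                           mode = c("ca_pair", "min_heavy", "centroid")) {
  mode <- match.arg(mode)
  if (!length(groupA) || !length(groupB)) stop("empty atom group")
  if (mode == "ca_pair" && (length(groupA) != 1L || length(groupB) != 1L))
    stop("ca_pair mode requires exactly one atom per group (got ",
         length(groupA), " and ", length(groupB), ")")
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    m <- frameCoords(traj, f)
    A <- m[groupA, , drop = FALSE]; B <- m[groupB, , drop = FALSE]
    switch(mode,
      ca_pair = sqrt(sum((A[1, ] - B[1, ])^2)),
      centroid = sqrt(sum((colMeans(A) - colMeans(B))^2)),
      min_heavy = {
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
        sqrt(max(min(d2), 0))
      })
  }, numeric(1))
  .newSeries(trajTimes(traj), vals)
}

#' Ideal B-form strand of phosphate (and base-centroid) pseudo-atoms
#'
#' Places phosphate k (k = 0..n-1) at helical angle k*twist, height
#' k*rise and radius pRadius. The adjacent P-P distance then equals the
#' closed-form chord \eqn{\sqrt{(2 r \sin(twist/2))^2 + rise^2}}; the
#' defaults reproduce the canonical ~7 A spacing used as the
#' one-nucleotide translocation yardstick.
#'
#' @param n number of nucleotides (>= 2)
#' @param twist helical twist per step, degrees
#' @param rise rise per step, Angstrom
#' @param pRadius radial displacement of P from the helix axis, Angstrom
#' @param withBase also place base-centroid pseudo-atoms at
#'   \code{baseRadius}
#' @param baseRadius radial position of the base centroids, Angstrom
#' @return list(P = n x 3 matrix, base = n x 3 matrix or NULL,
#'   spacing = closed-form adjacent P-P distance)
#' @export
buildBFormStrand <- function(n, twist = 36, rise = 3.38, pRadius = 9.93,
                             withBase = FALSE, baseRadius = 4.5) {
  stopifnot(n >= 2, twist > 0 || twist == 0, twist < 360, rise > 0,
            pRadius > 0)
  k <- seq_len(n) - 1
  th <- k * twist * pi / 180
  P <- cbind(pRadius * cos(th), pRadius * sin(th), k * rise)
  base <- if (withBase)
    cbind(baseRadius * cos(th), baseRadius * sin(th), k * rise)
  else NULL
  spacing <- sqrt((2 * pRadius * sin(twist * pi / 360))^2 + rise^2)
  list(P = P, base = base, spacing = spacing)
}

#' Windowed mean and standard deviation of a time series
#'
#' Frames with t_start <= t <= t_end (closed interval) enter the
#' statistics; the SD is the per-frame standard deviation over the
#' window.
#'
#' @param series data.frame(time_ns, value)
#' @param window numeric length 2, (t_start, t_end) in ns
#' @return list(mean, sd, window, nFrames)
#' @export
seriesStat <- function(series, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- series$time_ns >= window[1] & series$time_ns <= window[2]
  if (sum(sel) < 2L)
    stop(sprintf("window [%.3f, %.3f] ns covers %d frame(s); at least 2 required",
                 window[1], window[2], sum(sel)))
  v <- series$value[sel]
  list(mean = mean(v), sd = stats::sd(v),
       window = as.numeric(window), nFrames = sum(sel))
}
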