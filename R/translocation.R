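## Inference core: pore geometry, equilibration windows, per-nucleotide
## displacement tracks, translocation criterion, stage segmentation,
## representative frames, bend metric and replica classification.

#' Pore analysis configuration
#'
#' Residue assignments and thresholds for the entry-pore observables.
#' Defaults follow the helicase pore convention: pore width proxied by
#' the Calpha(H135)-Calpha(L220) distance, the Arch/lobe-1 gap by
#' Calpha(R380)-Calpha(L220), the minimum gap by the R380 side chain
#' against the lobe-1 helix (residues 215-221), and the one-nucleotide
#' translocation yardstick by the ~7 A B-form adjacent phosphate
#' spacing.
#'
#' @param widthPair residue numbers of the pore-width Calpha pair
#' @param gapPair residue numbers of the gap Calpha pair
#' @param gapResidue residue whose side chain defines the minimum gap
#' @param gapGroupResidues lobe-1 helix residue range for the minimum
#'   gap
#' @param fitSelection selection string for the pore superposition fit
#'   set (Calpha atoms of the three pore-forming domains)
#' @param sensorPockets named list of residue sets for the two base
#'   sensors (FeS pocket and lobe-1 helix)
#' @param prismAnchors named list of three residue ranges whose Calpha
#'   centroids span the pore-interior triangle
#' @param prismHalfDepth prism extrusion half-depth, Angstrom
#' @param bdnaSpacing B-form adjacent P-P spacing, Angstrom
#' @param translocationFactor backbone-translocation threshold as a
#'   fraction of \code{bdnaSpacing}
#' @param baseRmsdCut heavy-atom RMSD threshold for base translocation,
#'   Angstrom
#' @return list of class "PoreConfig"
#' @export
poreConfig <- function(widthPair = c(135L, 220L),
                       gapPair = c(380L, 220L),
                       gapResidue = 380L,
                       gapGroupResidues = 215:221,
                       fitSelection = "calpha and domain FeS Arch ATPase1",
                       sensorPockets = list(
                         FeS = c(135L, 139L, 140L, 141L, 158L, 161L,
                                 192L, 193L, 384L),
                         lobe1 = 215:221),
                       prismAnchors = list(FeS = 128:138,
                                           Arch = 376:384,
                                           lobe1 = 215:221),
                       prismHalfDepth = 6.0,
                       bdnaSpacing = 7.0,
                       translocationFactor = 0.8,
                       baseRmsdCut = 5.0) {
  stopifnot(bdnaSpacing > 0, translocationFactor > 0, baseRmsdCut > 0,
            length(prismAnchors) == 3L)
  structure(list(widthPair = widthPair, gapPair = gapPair,
                 gapResidue = gapResidue,
                 gapGroupResidues = gapGroupResidues,
                 fitSelection = fitSelection,
                 sensorPockets = sensorPockets,
                 prismAnchors = prismAnchors,
                 prismHalfDepth = prismHalfDepth,
                 bdnaSpacing = bdnaSpacing,
                 translocationFactor = translocationFactor,
                 baseRmsdCut = baseRmsdCut),
            class = "PoreConfig")
}

.caOf <- function(topology, resno) {
  resolveSelection(topology, sprintf("name CA and resid %d", resno))
}

#' Pore geometry time series
#'
#' Width = Calpha-Calpha of the width pair; gap = Calpha-Calpha of the
#' gap pair; minimum gap = minimum heavy-atom distance between the gap
#' residue's side chain and the lobe-1 helix residues. All are internal
#' distances; no superposition is involved.
#'
#' @param traj a Trajectory
#' @param config a \code{\link{poreConfig}}
#' @return list(width, gap, minGap) of data.frame(time_ns, value)
#' @export
poreGeometrySeries <- function(traj, config = poreConfig()) {
  topo <- topology(traj)
  width <- distanceSeries(traj, .caOf(topo, config$widthPair[1]),
                          .caOf(topo, config$widthPair[2]), "ca_pair")
  gap <- distanceSeries(traj, .caOf(topo, config$gapPair[1]),
                        .caOf(topo, config$gapPair[2]), "ca_pair")
  side <- resolveSelection(topo, sprintf(
    "resid %d and heavy and not backbone", config$gapResidue))
  helix <- resolveSelection(topo, sprintf(
    "resid %d:%d and heavy", min(config$gapGroupResidues),
    max(config$gapGroupResidues)))
  minGap <- distanceSeries(traj, side, helix, "min_heavy")
  list(width = width, gap = gap, minGap = minGap)
}

#' Detect the equilibration window of a replica
#'
#' Returns the earliest t_start after which every input series is flat:
#' over a sliding window of 10% of the trajectory length, the absolute
#' linear slope stays below 0.1 A per 100 ns from t_start to the end.
#' t_end is the final time. A user-supplied window overrides detection;
#' when no plateau is found the final 40% of frames is used with a
#' warning.
#'
#' @param seriesList list of data.frame(time_ns, value) on a common
#'   time base
#' @param override numeric length 2 (ns); returned verbatim if given
#' @param windowFrac sliding-window length as a fraction of the
#'   trajectory
#' @param slopeTol absolute slope tolerance, Angstrom per ns
#' @return numeric length 2: (t_start, t_end) in ns
#' @export
equilibrationWindow <- function(seriesList, override = NULL,
                                windowFrac = 0.1, slopeTol = 0.001) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2L)
    return(as.numeric(override))
  }
  if (length(seriesList) < 1L) stop("at least one series is required")
  tt <- seriesList[[1]]$time_ns
  for (s in seriesList)
    if (!isTRUE(all.equal(s$time_ns, tt)))
      stop("series do not share a common time base")
  n <- length(tt)
  w <- max(3L, ceiling(windowFrac * n))
  nW <- n - w + 1L
  if (nW < 1L) stop("trajectory too short for the sliding window")
  flat <- rep(TRUE, nW)
  for (s in seriesList) {
    v <- s$value
    for (i in seq_len(nW)) {
      if (!flat[i]) next
      idx <- i:(i + w - 1L)
      x <- tt[idx]; y <- v[idx]
      slope <- stats::cov(x, y) / stats::var(x)
      if (abs(slope) >= slopeTol) flat[i] <- FALSE
    }
  }
  ## earliest start index from which every subsequent window is flat
  ok <- rev(cumprod(rev(flat))) > 0
  if (any(ok)) {
    c(tt[which(ok)[1]], tt[n])
  } else {
    warning("no plateau found; falling back to the final 40% of frames")
    c(tt[max(1L, ceiling(0.6 * n))], tt[n])
  }
}

#' Per-nucleotide displacement track after pore superposition
#'
#' Per frame: superpose on the pore fit set, then record (i) the
#' displacement of the nucleotide's P atom from its reference position,
#' (ii) the heavy-atom RMSD of the nucleotide versus the reference
#' (no refit on the nucleotide), and (iii) the base-centroid position.
#'
#' @param traj a Trajectory
#' @param reference n x 3 reference frame coordinates
#' @param nucleotide residue number of the tracked nucleotide
#' @param config a \code{\link{poreConfig}}
#' @return list of class "NucleotideTrack": nucleotide, pDisplacement
#'   and heavyRmsd series, baseCentroids matrix (n_frames x 3)
#' @export
nucleotideTrack <- function(traj, reference, nucleotide,
                            config = poreConfig()) {
  topo <- topology(traj)
  fitIdx <- resolveSelection(topo, config$fitSelection)
  heavyIdx <- resolveSelection(topo, sprintf("resid %d and heavy",
                                             nucleotide))
  a <- atomTable(traj)
  heavyIdx <- heavyIdx[.isNucRow(a)[heavyIdx]]
  if (!length(heavyIdx)) stop("residue ", nucleotide,
                              " is not a nucleotide")
  pIdx <- heavyIdx[a$name[heavyIdx] == "P"]
  if (!length(pIdx))
    warning("nucleotide ", nucleotide,
            " has no P atom; heavy-atom track only")
  baseIdx <- tryCatch(
    intersect(heavyIdx, resolveSelection(topo, "base")),
    error = function(e) integer())
  nf <- nFrames(traj)
  pd <- rep(NA_real_, nf); hr <- numeric(nf)
  bc <- matrix(NA_real_, nf, 3)
  refH <- reference[heavyIdx, , drop = FALSE]
  for (f in seq_len(nf)) {
    fit <- kabschSuperpose(frameCoords(traj, f), reference, fitIdx)
    m <- fit$coords
    if (length(pIdx))
      pd[f] <- sqrt(sum((m[pIdx[1], ] - reference[pIdx[1], ])^2))
    hr[f] <- sqrt(mean(rowSums((m[heavyIdx, , drop = FALSE] - refH)^2)))
    if (length(baseIdx))
      bc[f, ] <- colMeans(m[baseIdx, , drop = FALSE])
  }
  structure(list(nucleotide = nucleotide,
                 pDisplacement = if (length(pIdx))
                   .newSeries(trajTimes(traj), pd) else NULL,
                 heavyRmsd = .newSeries(trajTimes(traj), hr),
                 baseCentroids = bc),
            class = "NucleotideTrack")
}

## Pore-interior test: the triangular prism spanned by the three
## domain-anchor Calpha centroids, extruded +-halfDepth along the
## triangle normal.
.prismAnchorPoints <- function(topology, reference, config) {
  t(vapply(config$prismAnchors, function(rng) {
    idx <- resolveSelection(topology, sprintf("name CA and resid %d:%d",
                                              min(rng), max(rng)))
    colMeans(reference[idx, , drop = FALSE])
  }, numeric(3)))
}

.insidePrism <- function(point, anchors, halfDepth) {
  a <- anchors[1, ]; b <- anchors[2, ]; c <- anchors[3, ]
  n <- .cross3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) return(FALSE)
  n <- n / nn
  h <- sum((point - a) * n)
  if (abs(h) > halfDepth) return(FALSE)
  p <- point - h * n
  ## barycentric coordinates of the in-plane projection
  v0 <- c - a; v1 <- b - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  u >= 0 && v >= 0 && (u + v) <= 1
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Classify the behavior of a tracked nucleotide
#'
#' Label assignment over the analysis window:
#' \itemize{
#'   \item backbone_translocation: windowed mean P displacement >=
#'     translocationFactor * bdnaSpacing;
#'   \item base_translocation: else, windowed mean heavy-atom RMSD >=
#'     baseRmsdCut AND the windowed mean base centroid lies inside the
#'     pore-interior prism;
#'   \item blocked: otherwise.
#' }
#'
#' @param track a \code{\link{nucleotideTrack}}
#' @param window numeric length 2 (ns)
#' @param topology the system Topology
#' @param reference reference frame coordinates (for the prism anchors)
#' @param config a \code{\link{poreConfig}}
#' @return list(label, evidence)
#' @export
classifyBehavior <- function(track, window, topology, reference,
                             config = poreConfig()) {
  thr <- config$translocationFactor * config$bdnaSpacing
  pStat <- if (!is.null(track$pDisplacement))
    seriesStat(track$pDisplacement, window) else NULL
  hStat <- seriesStat(track$heavyRmsd, window)
  sel <- track$heavyRmsd$time_ns >= window[1] &
         track$heavyRmsd$time_ns <= window[2]
  baseMean <- if (all(is.na(track$baseCentroids[sel, 1]))) NULL
              else colMeans(track$baseCentroids[sel, , drop = FALSE])
  anchors <- .prismAnchorPoints(topology, reference, config)
  inPore <- !is.null(baseMean) &&
    .insidePrism(baseMean, anchors, config$prismHalfDepth)
  label <- if (!is.null(pStat) && pStat$mean >= thr)
    "backbone_translocation"
  else if (hStat$mean >= config$baseRmsdCut && inPore)
    "base_translocation"
  else "blocked"
  list(label = label,
       evidence = list(
         meanPDisplacement = if (is.null(pStat)) NA_real_ else pStat$mean,
         meanHeavyRmsd = hStat$mean,
         baseCentroidInPore = inPore,
         translocationThreshold = thr,
         baseRmsdCut = config$baseRmsdCut,
         window = as.numeric(window)))
}

#' Contact-fingerprint stage segmentation
#'
#' Computes a per-frame binary contact fingerprint over the supplied
#' residue-nucleotide pairs (contact = minimum heavy-atom distance <=
#' contactCutoff), smooths each pair series with a majority filter of
#' width 5% of the frames, and emits a stage boundary wherever the
#' smoothed fingerprint changes to a state that persists at least
#' minDwell.
#'
#' @param traj a Trajectory
#' @param pairs data.frame(residue, nucleotide) of key contacts
#' @param contactCutoff heavy-atom contact distance, Angstrom
#' @param minDwell minimum dwell time of a stage, ns; default 5% of
#'   the trajectory length
#' @param filterFrac majority-filter width as a fraction of frames
#' @return list of class "StageSegmentation": boundaries (ns), stages
#'   data.frame(start, end), fingerprints (stages x pairs 0/1 matrix),
#'   pairLabels, minDwell
#' @export
segmentStages <- function(traj, pairs, contactCutoff = 4.0,
                          minDwell = NULL, filterFrac = 0.05) {
  stopifnot(nrow(pairs) >= 1L)
  topo <- topology(traj)
  tt <- trajTimes(traj)
  n <- length(tt)
  if (is.null(minDwell)) minDwell <- 0.05 * (tt[n] - tt[1])
  contact <- matrix(FALSE, n, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ri <- resolveSelection(topo, sprintf("resid %d and heavy",
                                         pairs$residue[p]))
    ni <- resolveSelection(topo, sprintf("resid %d and heavy",
                                         pairs$nucleotide[p]))
    a <- atomTable(traj)
    ni <- ni[.isNucRow(a)[ni]]
    ri <- setdiff(ri, ni)
    d <- distanceSeries(traj, ri, ni, "min_heavy")
    contact[, p] <- d$value <= contactCutoff
  }
  ## majority filter, odd width >= 1
  w <- max(1L, round(filterFrac * n))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L) {
    half <- (w - 1L) %/% 2L
    sm <- contact
    for (p in seq_len(ncol(contact))) {
      x <- contact[, p]
      for (i in seq_len(n)) {
        idx <- max(1L, i - half):min(n, i + half)
        sm[i, p] <- mean(x[idx]) > 0.5
      }
    }
    contact <- sm
  }
  fp <- apply(contact, 1L, function(r)
    paste(as.integer(r), collapse = ""))
  r <- rle(fp)
  ## absorb runs shorter than the dwell into the preceding stage
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  keep <- rep(TRUE, length(r$values))
  for (k in seq_along(r$values)[-1L]) {
    dwell <- tt[ends[k]] - tt[starts[k]]
    if (dwell < minDwell) keep[k] <- FALSE
  }
  ## merge consecutive identical stages after dropping flickers
  segs <- list(); cur <- NULL
  for (k in seq_along(r$values)) {
    if (!keep[k]) {
      if (!is.null(cur)) cur$endIdx <- ends[k]
      next
    }
    if (!is.null(cur) && cur$fp == r$values[k]) {
      cur$endIdx <- ends[k]
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- list(fp = r$values[k], startIdx = starts[k],
                  endIdx = ends[k])
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
  if (!length(segs))
    segs <- list(list(fp = fp[1], startIdx = 1L, endIdx = n))
  bidx <- vapply(segs[-1L], function(s) s$startIdx, 0L)
  fps <- do.call(rbind, lapply(segs, function(s)
    as.integer(strsplit(s$fp, "")[[1]])))
  stages <- data.frame(
    start = tt[vapply(segs, function(s) s$startIdx, 0L)],
    end = tt[vapply(segs, function(s) s$endIdx, 0L)])
  labels <- paste0(pairs$residue, "-", pairs$nucleotide)
  colnames(fps) <- labels
  structure(list(boundaries = if (length(bidx)) tt[bidx] else numeric(),
                 stages = stages, fingerprints = fps,
                 pairLabels = labels, minDwell = minDwell),
            class = "StageSegmentation")
}

#' Medoid representative frame of a windowed ensemble
#'
#' The window frame minimizing the summed pairwise RMSD (after mutual
#' superposition on the selection) to all other window frames; ties
#' break to the earliest time.
#'
#' @param traj a Trajectory
#' @param selection selection string for both fit and measure atoms
#' @param window numeric length 2 (ns)
#' @return integer frame index (into the full trajectory)
#' @export
representativeFrame <- function(traj, selection, window) {
  tt <- trajTimes(traj)
  fr <- which(tt >= window[1] & tt <= window[2])
  if (length(fr) < 2L) stop("window must contain at least 2 frames")
  idx <- resolveSelection(topology(traj), selection)
  nf <- length(fr)
  D <- matrix(0, nf, nf)
  coords <- lapply(fr, function(f) frameCoords(traj, f))
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    fit <- kabschSuperpose(coords[[i]], coords[[j]], idx)
    d <- sqrt(mean(rowSums((fit$coords[idx, , drop = FALSE] -
                            coords[[j]][idx, , drop = FALSE])^2)))
    D[i, j] <- d; D[j, i] <- d
  }
  fr[which.min(rowSums(D))]
}

#' Cross-loop phosphodiester distance series (DNA bend metric)
#'
#' For three consecutive P atoms i-1, i, i+1 the series is the
#' distance between the two outer P atoms; a bend is called when its
#' windowed mean is <= bendFactor * the adjacent B-form spacing
#' (default 1.3 x 7.0 = 9.1 A).
#'
#' @param traj a Trajectory
#' @param pResnos residue numbers of three consecutive nucleotides
#' @return data.frame(time_ns, value)
#' @export
bendSeries <- function(traj, pResnos) {
  stopifnot(length(pResnos) == 3L)
  topo <- topology(traj)
  pOuter <- lapply(pResnos[c(1, 3)], function(r)
    resolveSelection(topo, sprintf("name P and resid %d", r)))
  distanceSeries(traj, pOuter[[1]], pOuter[[2]], "ca_pair")
}

#' Bend predicate on a windowed cross-loop distance
#' @param series output of \code{\link{bendSeries}}
#' @param window numeric length 2 (ns)
#' @param spacing adjacent B-form P-P spacing, Angstrom
#' @param bendFactor threshold multiplier
#' @export
bendPredicate <- function(series, window, spacing = 7.0,
                          bendFactor = 1.3) {
  seriesStat(series, window)$mean <= bendFactor * spacing
}

#' Population table over replica reports
#'
#' Per-label counts and percentages (nearest integer percent), in the
#' fixed order backbone_translocation, base_translocation, blocked.
#'
#' @param reports list of \linkS4class{TranslocationReport} (or of
#'   lists with a \code{$label$label} field)
#' @return data.frame(label, count, percent)
#' @export
replicaSummary <- function(reports) {
  stopifnot(length(reports) >= 1L)
  labs <- vapply(reports, function(r) {
    if (is(r, "TranslocationReport")) r@label$label else r$label$label
  }, character(1))
  count <- vapply(.LABELS, function(l) sum(labs == l), 0L)
  data.frame(label = .LABELS, count = as.integer(count),
             percent = as.integer(round(100 * count / length(labs))),
             row.names = NULL)
}
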