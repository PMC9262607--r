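## Geometric detection and occupancy quantification of hydrogen bonds,
## cation-pi / methyl-pi contacts, and van-der-Waals contact counts
## between protein residues and nucleotides.

#' Hydrogen-bond criterion
#'
#' @param daCutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#' @param dhaMinAngle minimum D-H...A angle, degrees
#' @param hydrogenMode "explicit" uses hydrogens present in the
#'   topology; "inferred" places H on the D->A axis at 1.0 A so the
#'   angle test passes trivially (distance-only criterion)
#' @return list of class "HBondCriterion"
#' @export
hbondCriterion <- function(daCutoff = 3.5, dhaMinAngle = 135,
                           hydrogenMode = c("explicit", "inferred")) {
  stopifnot(daCutoff > 0, dhaMinAngle >= 0, dhaMinAngle <= 180)
  structure(list(daCutoff = daCutoff, dhaMinAngle = dhaMinAngle,
                 hydrogenMode = match.arg(hydrogenMode)),
            class = "HBondCriterion")
}

## Donor / acceptor role templates: standard amino acids, standard
## nucleotides, and the tandem-lesion residue T64 (both rings' O2/O4
## acceptors and ring N3-H donors, carried with 5/3 name prefixes).
.roleTemplates <- function() {
  prot_don <- rbind(
    data.frame(resname = .AMINO3, name = "N"),
    data.frame(resname = "ARG", name = c("NE", "NH1", "NH2")),
    data.frame(resname = "LYS", name = "NZ"),
    data.frame(resname = "HIS", name = c("ND1", "NE2")),
    data.frame(resname = c("SER", "THR", "TYR"),
               name = c("OG", "OG1", "OH")),
    data.frame(resname = c("ASN", "GLN"), name = c("ND2", "NE2")),
    data.frame(resname = "TRP", name = "NE1"),
    data.frame(resname = "CYS", name = "SG"))
  prot_acc <- rbind(
    data.frame(resname = .AMINO3, name = "O"),
    data.frame(resname = "ASP", name = c("OD1", "OD2")),
    data.frame(resname = "GLU", name = c("OE1", "OE2")),
    data.frame(resname = "ASN", name = "OD1"),
    data.frame(resname = "GLN", name = "OE1"),
    data.frame(resname = "HIS", name = c("ND1", "NE2")),
    data.frame(resname = c("SER", "THR", "TYR"),
               name = c("OG", "OG1", "OH")))
  nuc <- setdiff(.NUC3, .LESION_RES)
  dna_acc <- rbind(
    expand.grid(resname = nuc,
                name = c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'"),
                stringsAsFactors = FALSE),
    data.frame(resname = c("DT", "T", "DT5", "DT3"), name = "O2"),
    data.frame(resname = c("DT", "T", "DT5", "DT3"), name = "O4"),
    data.frame(resname = c("DC", "C"), name = "O2"),
    data.frame(resname = c("DC", "C"), name = "N3"),
    expand.grid(resname = c("DA", "A"), name = c("N1", "N3", "N7"),
                stringsAsFactors = FALSE),
    expand.grid(resname = c("DG", "G"), name = c("O6", "N3", "N7"),
                stringsAsFactors = FALSE))
  dna_don <- rbind(
    data.frame(resname = c("DT", "T", "DT5", "DT3"), name = "N3"),
    data.frame(resname = c("DA", "A"), name = "N6"),
    expand.grid(resname = c("DG", "G"), name = c("N1", "N2"),
                stringsAsFactors = FALSE),
    data.frame(resname = c("DC", "C"), name = "N4"))
  les_acc <- data.frame(resname = .LESION_RES,
                        name = c(outer(c("5", "3"), c("O2", "O4", "N3"),
                                       paste0)))
  les_bb_acc <- data.frame(resname = .LESION_RES,
                           name = c("OP1", "OP2", "O5'", "O3'", "O4'"))
  les_don <- data.frame(resname = .LESION_RES, name = c("5N3", "3N3"))
  list(donor = rbind(prot_don, dna_don, les_don),
       acceptor = rbind(prot_acc, dna_acc, les_acc, les_bb_acc))
}

.roleFlag <- function(atoms, tmpl) {
  paste(atoms$resname, atoms$name) %in% paste(tmpl$resname, tmpl$name)
}

#' Assign donor/acceptor roles from residue templates
#'
#' @param topology a Topology
#' @return data.frame with logical columns donor and acceptor, one row
#'   per atom
#' @export
hbondRoles <- function(topology) {
  tm <- .roleTemplates()
  a <- topology@atoms
  data.frame(donor = .roleFlag(a, tm$donor),
             acceptor = .roleFlag(a, tm$acceptor))
}

## Map each hydrogen to its covalently bound donor-capable heavy atom
## (N/O/S): nearest such atom of the same residue within 1.3 A in the
## given frame. C-H hydrogens are irrelevant to the donor geometry.
.assignHydrogens <- function(topology, coords) {
  a <- topology@atoms
  h <- which(a$element == "H")
  out <- integer(0)
  if (!length(h)) return(out)
  heavy <- which(a$element %in% c("N", "O", "S"))
  map <- rep(NA_integer_, length(h))
  for (k in seq_along(h)) {
    i <- h[k]
    cand <- heavy[a$chain[heavy] == a$chain[i] &
                  a$resno[heavy] == a$resno[i]]
    if (!length(cand)) next
    d <- sqrt(rowSums((coords[cand, , drop = FALSE] -
                       matrix(coords[i, ], length(cand), 3,
                              byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= 1.3) map[k] <- cand[j]
  }
  structure(map, names = as.character(h))
}

.angleDeg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, c1))) * 180 / pi
}

#' Detect satisfied hydrogen bonds in one frame
#'
#' A donor-acceptor pair (in different residues) is satisfied iff the
#' D-A heavy-atom distance is <= the cutoff AND the D-H...A angle at
#' some donor hydrogen is >= the minimum angle. In "inferred" mode (or
#' for donors with no resolvable hydrogen in "explicit" mode with
#' \code{fallback = TRUE}) the hydrogen is placed on the D->A axis so
#' the angle test passes trivially.
#'
#' @param coords n x 3 frame coordinates
#' @param topology a Topology
#' @param donors integer donor heavy-atom positions
#' @param acceptors integer acceptor heavy-atom positions
#' @param criterion an \code{\link{hbondCriterion}}
#' @param hydrogenMap optional precomputed hydrogen assignment from the
#'   reference frame (named integer: H position -> heavy position)
#' @return data.frame(donor, acceptor) of satisfied pairs
#' @export
detectHBonds <- function(coords, topology, donors, acceptors,
                         criterion = hbondCriterion(),
                         hydrogenMap = NULL) {
  a <- topology@atoms
  roles <- hbondRoles(topology)
  keep <- roles$donor[donors]
  if (any(!keep)) {
    warning("excluding ", sum(!keep),
            " donor atom(s) with no role template")
    donors <- donors[keep]
  }
  keep <- roles$acceptor[acceptors]
  if (any(!keep)) {
    warning("excluding ", sum(!keep),
            " acceptor atom(s) with no role template")
    acceptors <- acceptors[keep]
  }
  if (!length(donors) || !length(acceptors))
    return(data.frame(donor = integer(), acceptor = integer()))
  explicit <- criterion$hydrogenMode == "explicit"
  if (explicit && is.null(hydrogenMap))
    hydrogenMap <- .assignHydrogens(topology, coords)
  .hbCore(coords, a, donors, acceptors, criterion, hydrogenMap,
          explicit)
}

## Distance/angle evaluation shared by detectHBonds and the windowed
## occupancy loop (roles already filtered, no warnings).
.hbCore <- function(coords, a, donors, acceptors, criterion,
                    hydrogenMap, explicit) {
  hOf <- function(d) {
    if (!explicit || !length(hydrogenMap)) return(integer())
    as.integer(names(hydrogenMap))[!is.na(hydrogenMap) &
                                   hydrogenMap == d]
  }
  D <- coords[donors, , drop = FALSE]
  A <- coords[acceptors, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * tcrossprod(D, A)
  hits <- which(d2 <= criterion$daCutoff^2 & d2 > 1e-6, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    di <- donors[hits[r, 1]]; ai <- acceptors[hits[r, 2]]
    if (a$chain[di] == a$chain[ai] && a$resno[di] == a$resno[ai]) next
    ok <- TRUE
    hs <- hOf(di)
    if (explicit && length(hs)) {
      ang <- vapply(hs, function(hi)
        .angleDeg(coords[di, ] - coords[hi, ],
                  coords[ai, ] - coords[hi, ]), numeric(1))
      ok <- any(ang >= criterion$dhaMinAngle)
    }
    if (ok) out[[length(out) + 1L]] <- c(di, ai)
  }
  if (!length(out)) return(data.frame(donor = integer(),
                                      acceptor = integer()))
  m <- do.call(rbind, out)
  data.frame(donor = m[, 1], acceptor = m[, 2])
}

#' Hydrogen-bond occupancies over a trajectory window
#'
#' Occupancy is the satisfied-frame count divided by the window frame
#' count, per donor-acceptor pair; pairs never satisfied are omitted.
#'
#' @param traj a Trajectory
#' @param donors,acceptors integer atom positions
#' @param criterion an \code{\link{hbondCriterion}}
#' @param window numeric length 2 (ns); NULL means all frames
#' @return data.frame(donor, acceptor, occupancy)
#' @export
hbondOccupancy <- function(traj, donors, acceptors,
                           criterion = hbondCriterion(), window = NULL) {
  tt <- trajTimes(traj)
  fr <- if (is.null(window)) seq_along(tt)
        else which(tt >= window[1] & tt <= window[2])
  if (!length(fr)) stop("window contains no frames")
  topo <- topology(traj)
  explicit <- criterion$hydrogenMode == "explicit"
  hmap <- if (explicit)
    .assignHydrogens(topo, frameCoords(traj, fr[1])) else NULL
  ## filter roles once for the whole window
  roles <- hbondRoles(topo)
  donors <- donors[roles$donor[donors]]
  acceptors <- acceptors[roles$acceptor[acceptors]]
  a <- topo@atoms
  counts <- new.env(parent = emptyenv())
  for (f in fr) {
    hb <- .hbCore(frameCoords(traj, f), a, donors, acceptors,
                  criterion, hmap, explicit)
    if (nrow(hb)) {
      keys <- paste(hb$donor, hb$acceptor)
      for (k in keys)
        assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L,
               counts)
    }
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(donor = integer(), acceptor = integer(),
                      occupancy = numeric()))
  m <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(donor = as.integer(m[, 1]),
                    acceptor = as.integer(m[, 2]),
                    occupancy = vapply(keys, get, numeric(1),
                                       envir = counts) / length(fr))
  out <- out[order(out$donor, out$acceptor), ]
  rownames(out) <- NULL
  out
}

#' Total hydrogen-bond numbers per residue-nucleotide pair
#'
#' Groups pair occupancies by (protein residue, nucleotide, moiety) and
#' sums them; the total may exceed 1. The moiety (backbone vs base) is
#' that of the nucleotide-side atom. A "panel total" over a residue
#' list is the plain sum of its group totals.
#'
#' @param occupancies output of \code{\link{hbondOccupancy}}
#' @param topology a Topology
#' @return data.frame(residue, resname, nucleotide, nucname, moiety,
#'   totalHB)
#' @export
totalHBNumber <- function(occupancies, topology) {
  a <- topology@atoms
  if (!nrow(occupancies))
    return(data.frame(residue = integer(), resname = character(),
                      nucleotide = integer(), nucname = character(),
                      moiety = character(), totalHB = numeric()))
  nucRow <- .isNucRow(a)
  rows <- lapply(seq_len(nrow(occupancies)), function(r) {
    d <- occupancies$donor[r]; ac <- occupancies$acceptor[r]
    dn <- nucRow[d]; an <- nucRow[ac]
    if (dn == an)
      stop(sprintf("pair %s(%s%d)-%s(%s%d) does not span protein and nucleotide",
                   a$name[d], a$resname[d], a$resno[d],
                   a$name[ac], a$resname[ac], a$resno[ac]))
    nuc <- if (dn) d else ac
    prot <- if (dn) ac else d
    moiety <- if (a$name[nuc] %in% .DNA_BB) "backbone" else "base"
    data.frame(residue = a$resno[prot], resname = a$resname[prot],
               nucleotide = a$resno[nuc], nucname = a$resname[nuc],
               moiety = moiety, occupancy = occupancies$occupancy[r])
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(occupancy ~ residue + resname + nucleotide +
                            nucname + moiety, data = df, FUN = sum)
  names(agg)[names(agg) == "occupancy"] <- "totalHB"
  agg <- agg[order(agg$residue, agg$nucleotide, agg$moiety), ]
  rownames(agg) <- NULL
  agg
}

#' Cation-pi or methyl-pi contact series
#'
#' Per frame the contact is satisfied iff the distance from the cation
#' (Arg CZ / Lys NZ) or methyl carbon to the ring centroid is within
#' the cutoff AND the angle between the ring normal and the
#' centroid-to-atom vector is <= maxAngle. Default cutoffs: 6.0 A
#' (cation-pi), 4.6 A (methyl-pi); 45 degrees.
#'
#' @param traj a Trajectory
#' @param kind "cation_pi" or "methyl_pi"
#' @param atom integer position of the cation / methyl-carbon atom
#' @param ringAtoms integer positions of the ring atoms (>= 5)
#' @param cutoff distance cutoff, Angstrom; NULL picks the default for
#'   \code{kind}
#' @param maxAngle maximum axial angle, degrees
#' @return list of class "PiContact": kind, atom, ringAtoms, distance
#'   series, satisfied logical vector, fraction
#' @export
piContactSeries <- function(traj, kind = c("cation_pi", "methyl_pi"),
                            atom, ringAtoms, cutoff = NULL,
                            maxAngle = 45) {
  kind <- match.arg(kind)
  if (length(ringAtoms) < 5L) stop("ring atom set must have >= 5 atoms")
  if (is.null(cutoff)) cutoff <- if (kind == "cation_pi") 6.0 else 4.6
  a <- atomTable(traj)
  if (kind == "cation_pi" &&
      !(a$name[atom] %in% c("CZ", "NZ")))
    stop("cation atom must be Arg CZ or Lys NZ, got ", a$name[atom])
  if (kind == "methyl_pi" && a$element[atom] != "C")
    stop("methyl atom must be a carbon")
  nf <- nFrames(traj)
  dist <- numeric(nf); sat <- logical(nf)
  for (f in seq_len(nf)) {
    m <- frameCoords(traj, f)
    ring <- m[ringAtoms, , drop = FALSE]
    cen <- colMeans(ring)
    sv <- svd(sweep(ring, 2, cen))
    if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
      stop("ring atoms are collinear: no plane normal")
    normal <- sv$v[, 3]
    v <- m[atom, ] - cen
    dist[f] <- sqrt(sum(v^2))
    ang <- .angleDeg(normal, v)
    ang <- min(ang, 180 - ang)
    sat[f] <- dist[f] <= cutoff && ang <= maxAngle
  }
  structure(list(kind = kind, atom = atom, ringAtoms = ringAtoms,
                 distance = .newSeries(trajTimes(traj), dist),
                 satisfied = sat, fraction = mean(sat)),
            class = "PiContact")
}

#' Van-der-Waals contact count series
#'
#' Per-frame count of cross heavy-atom pairs within the cutoff
#' (default 4.5 A).
#'
#' @param traj a Trajectory
#' @param groupA,groupB integer heavy-atom positions
#' @param cutoff contact distance, Angstrom
#' @return data.frame(time_ns, value) of contact counts
#' @export
vdwContactSeries <- function(traj, groupA, groupB, cutoff = 4.5) {
  if (!length(groupA) || !length(groupB)) stop("empty atom group")
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    m <- frameCoords(traj, f)
    A <- m[groupA, , drop = FALSE]; B <- m[groupB, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sum(d2 <= cutoff^2)
  }, numeric(1))
  .newSeries(trajTimes(traj), vals)
}

#' "Abolished" van-der-Waals contact predicate
#'
#' TRUE when the windowed mean contact count is below 1.0.
#' @param series output of \code{\link{vdwContactSeries}}
#' @param window numeric length 2 (ns)
#' @export
vdwAbolished <- function(series, window) {
  seriesStat(series, window)$mean < 1.0
}
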