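## Synthetic pore-ssDNA trajectory generator. Three rigid pseudo-domain
## clusters carry the canonical pore residues around a short B-form
## ssDNA track; scripted events (backbone hop, base flip, pore
## open/close, contact toggles) are planted with exact magnitudes so
## every downstream detector has an analytic ground truth.

.unit <- function(v) v / sqrt(sum(v^2))

.ringCoords <- function(center, normal, radius, n) {
  normal <- .unit(normal)
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(normal, ref))
  v <- .cross3(normal, u)
  t(vapply(seq_len(n) - 1L, function(j) {
    th <- 2 * pi * j / n
    center + radius * (cos(th) * u + sin(th) * v)
  }, numeric(3)))
}

## Internal builder: returns atom records + reference coordinates.
.buildScaffold <- function(lesion = FALSE, poreWidth = 16.7,
                           minGap = 2.8) {
  rows <- list(); pts <- list()
  add <- function(name, resname, resno, chain, p, element = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resname = resname, resno = resno, chain = chain,
      element = if (is.null(element)) .inferElement(name) else element,
      stringsAsFactors = FALSE)
    pts[[length(pts) + 1L]] <<- as.numeric(p)
  }
  zhat <- c(0, 0, 1)

  ## ---- ssDNA track (chain D, positions 0..3 at residues 39..42) ----
  twist <- 36 * pi / 180
  pR <- 9.93; rise <- 3.38; rb <- 4.5
  locus <- function(k) {
    th <- k * twist
    list(rhat = c(cos(th), sin(th), 0),
         that = c(-sin(th), cos(th), 0),
         z = (k - 1) * rise, th = th)
  }
  addBackbone <- function(resname, resno, k, withP = TRUE) {
    L <- locus(k)
    if (withP) {
      P <- pR * L$rhat + c(0, 0, L$z)
      add("P", resname, resno, "D", P)
      add("OP1", resname, resno, "D", P + 1.48 * L$rhat)
      add("OP2", resname, resno, "D", P + 1.48 * .unit(L$rhat + zhat))
    }
    C1 <- 7.0 * L$rhat + c(0, 0, L$z)
    add("C1'", resname, resno, "D", C1)
    add("O4'", resname, resno, "D", C1 + c(0, 0, 1.4))
  }
  addPyrimidineRing <- function(resname, resno, k, prefix = "",
                                zoff = 0, normal = NULL, methyl = TRUE) {
    L <- locus(k)
    if (is.null(normal)) normal <- L$rhat
    cen <- rb * L$rhat + c(0, 0, L$z + zoff)
    ring <- .ringCoords(cen, normal, 1.39, 6)
    nm <- paste0(prefix, c("N1", "C2", "N3", "C4", "C5", "C6"))
    for (j in 1:6) add(nm[j], resname, resno, "D", ring[j, ])
    add(paste0(prefix, "O2"), resname, resno, "D",
        ring[2, ] + 1.22 * .unit(ring[2, ] - cen))
    add(paste0(prefix, "O4"), resname, resno, "D",
        ring[4, ] + 1.22 * .unit(ring[4, ] - cen))
    if (methyl)
      add(paste0(prefix, "C7"), resname, resno, "D",
          ring[5, ] + 1.50 * .unit(ring[5, ] - cen))
    cen
  }
  ## position 0: 5'-terminal dA (no P)
  addBackbone("DA", 39L, 0, withP = FALSE)
  L0 <- locus(0)
  cen0 <- rb * L0$rhat + c(0, 0, L0$z)
  ringA <- .ringCoords(cen0, L0$rhat, 1.39, 6)
  for (j in 1:6) add(c("N1", "C2", "N3", "C4", "C5", "C6")[j],
                     "DA", 39L, "D", ringA[j, ])
  add("N6", "DA", 39L, "D", ringA[6, ] + 1.3 * .unit(ringA[6, ] - cen0))
  if (!lesion) {
    ## positions 1..3: dT; the position-1 base hangs below the pore
    ## plane (outside the pore, toward the lobe-1 side)
    addBackbone("DT", 40L, 1)
    addPyrimidineRing("DT", 40L, 1, zoff = -8)
    addBackbone("DT", 41L, 2)
    addPyrimidineRing("DT", 41L, 2)
    addBackbone("DT", 42L, 3)
    addPyrimidineRing("DT", 42L, 3)
    positions <- c("0" = 39L, "1" = 40L, "2" = 41L, "3" = 42L)
  } else {
    ## tandem lesion T64 spans positions 1-2: one P, two rings with
    ## 5/3 name prefixes, near-perpendicular normals
    addBackbone("T64", 40L, 1)
    addPyrimidineRing("T64", 40L, 1, prefix = "5", zoff = -8,
                      methyl = FALSE)
    addPyrimidineRing("T64", 40L, 2, prefix = "3", normal = zhat)
    addBackbone("DT", 42L, 3)
    addPyrimidineRing("DT", 42L, 3)
    positions <- c("0" = 39L, "1" = 40L, "3" = 42L)
  }

  ## ---- FeS cluster (chain A) --------------------------------------
  fes <- data.frame(
    resno = c(112L, 128L, 135L, 139L, 140L, 141L, 158L, 161L, 192L,
              193L, 196L),
    resname = c("ARG", "LYS", "HIS", "ALA", "SER", "TYR", "TYR", "PHE",
                "TYR", "PHE", "ARG"))
  caOfRes <- list()
  addBackboneProt <- function(resname, resno, CA, that) {
    add("N", resname, resno, "A", CA + 1.45 * that + c(0, 0, 0.4))
    add("CA", resname, resno, "A", CA)
    add("O", resname, resno, "A", CA - 1.45 * that + c(0, 0, -0.4))
    caOfRes[[as.character(resno)]] <<- CA
  }
  for (k in seq_len(nrow(fes))) {
    alpha <- (k - 1) * 6 * pi / 180
    ## the two DNA-anchor residues sit further out so their backward-
    ## built side chains do not fold onto their own backbone
    rad <- if (fes$resno[k] %in% c(192L, 196L)) 18 else 15
    CA <- c(rad * cos(alpha), rad * sin(alpha), -3 + 0.6 * (k - 1))
    inw <- -c(cos(alpha), sin(alpha), 0)
    that <- c(-sin(alpha), cos(alpha), 0)
    rn <- fes$resname[k]; ri <- fes$resno[k]
    addBackboneProt(rn, ri, CA, that)
    if (ri %in% c(192L, 196L)) next  # anchors built against the DNA below
    if (rn == "ARG") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      add("NE", rn, ri, "A", CA + 3.2 * inw)
      add("CZ", rn, ri, "A", CA + 4.0 * inw)
      add("NH1", rn, ri, "A", CA + 5.0 * inw + 0.6 * that)
      add("NH2", rn, ri, "A", CA + 5.0 * inw - 0.6 * that)
    } else if (rn == "LYS") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      add("NZ", rn, ri, "A", CA + 5.0 * inw)
    } else if (rn == "HIS") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      ring <- .ringCoords(CA + 3.5 * inw, inw, 1.15, 5)
      nm <- c("CG", "ND1", "CE1", "NE2", "CD2")
      for (j in 1:5) add(nm[j], rn, ri, "A", ring[j, ])
    } else if (rn %in% c("TYR", "PHE")) {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      ring <- .ringCoords(CA + 3.5 * inw, inw, 1.39, 6)
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (j in 1:6) add(nm[j], rn, ri, "A", ring[j, ])
      if (rn == "TYR")
        add("OH", rn, ri, "A", CA + 5.3 * inw)
    } else if (rn == "SER") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      add("OG", rn, ri, "A", CA + 2.6 * inw)
    } else if (rn == "ALA") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
    }
  }
  ## R196 guanidinium built backward from the dT2 phosphate oxygen so
  ## the planted hydrogen bond geometry is exact (D-A = 2.9 A)
  L2 <- locus(2)
  P2 <- pR * L2$rhat + c(0, 0, L2$z)
  OP1_2 <- P2 + 1.48 * L2$rhat
  CA196 <- caOfRes[["196"]]
  d196 <- .unit(CA196 - OP1_2)
  NH1 <- OP1_2 + 2.9 * d196
  CZ <- NH1 + 1.33 * d196
  perp196 <- .unit(.cross3(d196, zhat))
  add("CB", "ARG", 196L, "A", CA196 + 1.5 * .unit(CZ - CA196))
  add("NE", "ARG", 196L, "A", CZ + 1.33 * d196)
  add("CZ", "ARG", 196L, "A", CZ)
  add("NH1", "ARG", 196L, "A", NH1)
  add("NH2", "ARG", 196L, "A", CZ + 1.33 * perp196)
  ## Y192 hydroxyl built backward from the dA0 sugar oxygen (D-A = 2.9)
  O4p_0 <- 7.0 * L0$rhat + c(0, 0, L0$z + 1.4)
  CA192 <- caOfRes[["192"]]
  d192 <- .unit(CA192 - O4p_0)
  OH <- O4p_0 + 2.9 * d192
  cen192 <- OH + 1.4 * d192
  add("CB", "TYR", 192L, "A", CA192 + 1.5 * .unit(cen192 - CA192))
  ring <- .ringCoords(cen192, .unit(.cross3(d192, zhat)), 1.39, 6)
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (j in 1:6) add(nm[j], "TYR", 192L, "A", ring[j, ])
  add("OH", "TYR", 192L, "A", OH)

  ## ---- ATPase lobe 1 helix (PKIADLV, 215-221) ----------------------
  lobe <- data.frame(
    resno = 215:221,
    resname = c("PRO", "LYS", "ILE", "ALA", "ASP", "LEU", "VAL"))
  for (k in seq_len(nrow(lobe))) {
    ri <- lobe$resno[k]; rn <- lobe$resname[k]
    CA <- c((ri - 218) * 1.5, -13, 0)
    that <- c(1, 0, 0)
    addBackboneProt(rn, ri, CA, that)
    sc <- switch(rn,
      PRO = list(CB = CA + c(0, 1.5, 0), CG = CA + c(0.8, 2.3, 0),
                 CD = CA + c(-0.8, 2.3, 0)),
      LYS = list(CB = CA + c(0, 1.5, 0), CG = CA + c(0, 2.6, 0.4),
                 NZ = CA + c(0, 3.8, 0.8)),
      ILE = list(CB = CA + c(0, 1.5, 0), CG1 = CA + c(0.7, 2.4, 0),
                 CD1 = CA + c(0.7, 3.6, 0)),
      ALA = list(CB = CA + c(0, 1.5, 0)),
      ASP = list(CB = CA + c(0, 1.5, 0), CG = CA + c(0, 2.7, 0),
                 OD1 = CA + c(0.6, 3.6, 0), OD2 = CA + c(-0.6, 3.6, 0)),
      LEU = list(CB = CA + c(0, 1.5, 0), CG = CA + c(0, 2.7, 0),
                 CD1 = CA + c(0.8, 3.5, 0), CD2 = CA + c(-0.8, 3.5, 0)),
      VAL = list(CB = CA + c(0, 1.5, 0), CG1 = CA + c(0.7, 2.4, 0),
                 CG2 = CA + c(-0.7, 2.4, 0)))
    for (an in names(sc)) add(an, rn, ri, "A", sc[[an]])
  }

  ## ---- Arch cluster ------------------------------------------------
  arch <- data.frame(resno = c(377L, 380L, 384L, 402L),
                     resname = c("GLU", "ARG", "HIS", "ASN"))
  for (k in seq_len(nrow(arch))) {
    alpha <- (130 + (k - 1) * 12) * pi / 180
    CA <- c(14 * cos(alpha), 14 * sin(alpha), (k - 2) * 0.8)
    inw <- -c(cos(alpha), sin(alpha), 0)
    that <- c(-sin(alpha), cos(alpha), 0)
    ri <- arch$resno[k]; rn <- arch$resname[k]
    addBackboneProt(rn, ri, CA, that)
    if (rn == "GLU") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      add("CG", rn, ri, "A", CA + 2.6 * inw)
      add("OE1", rn, ri, "A", CA + 3.6 * inw + 0.6 * that)
      add("OE2", rn, ri, "A", CA + 3.6 * inw - 0.6 * that)
    } else if (rn == "HIS") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      ring <- .ringCoords(CA + 3.5 * inw, inw, 1.15, 5)
      nm <- c("CG", "ND1", "CE1", "NE2", "CD2")
      for (j in 1:5) add(nm[j], rn, ri, "A", ring[j, ])
    } else if (rn == "ASN") {
      add("CB", rn, ri, "A", CA + 1.5 * inw)
      add("CG", rn, ri, "A", CA + 2.6 * inw)
      add("OD1", rn, ri, "A", CA + 3.6 * inw + 0.5 * that)
      add("ND2", rn, ri, "A", CA + 3.6 * inw - 0.5 * that)
    }
    ## R380 side chain is placed after the lobe-1 width adjustment
  }

  atoms <- do.call(rbind, rows)
  coords <- do.call(rbind, pts)

  ## ---- enforce the planted pore width exactly ----------------------
  isLobe <- atoms$chain == "A" & atoms$resno >= 215 & atoms$resno <= 221
  ca135 <- coords[atoms$name == "CA" & atoms$resno == 135, ]
  i220 <- which(atoms$name == "CA" & atoms$resno == 220)
  u <- .unit(coords[i220, ] - ca135)
  target220 <- ca135 + poreWidth * u
  shift <- target220 - coords[i220, ]
  coords[isLobe, ] <- sweep(coords[isLobe, , drop = FALSE], 2, shift, "+")

  ## ---- R380 side chain: closest approach to D219/L220 = minGap -----
  od1 <- coords[atoms$name == "OD1" & atoms$resno == 219, ]
  ca380 <- coords[atoms$name == "CA" & atoms$resno == 380, ]
  ## guanidinium tip approaches the aspartate carboxylate from above the
  ## pore plane so no other atom pair undercuts the planted minimum
  u380 <- .unit(c(0, 0.2, 1))
  NH1 <- od1 + minGap * u380
  CZ380 <- NH1 + 1.33 * u380
  perp380 <- .unit(.cross3(u380, c(1, 0, 0)))
  extra <- list(
    CB = ca380 + 1.5 * .unit(CZ380 - ca380),
    NE = CZ380 + 1.33 * u380,
    CZ = CZ380, NH1 = NH1, NH2 = CZ380 + 1.33 * perp380)
  for (an in names(extra)) {
    atoms <- rbind(atoms, data.frame(
      name = an, resname = "ARG", resno = 380L, chain = "A",
      element = .inferElement(an), stringsAsFactors = FALSE))
    coords <- rbind(coords, extra[[an]])
  }

  ## residue-contiguous atom order (keeps residues blocked together)
  ord <- order(match(atoms$chain, c("A", "D")), atoms$resno,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, ]; coords <- coords[ord, , drop = FALSE]

  domainMap <- data.frame(
    domain = c("FeS", "ATPase1", "Arch", "DNA"),
    chain = c("A", "A", "A", "D"),
    start = c(100L, 210L, 370L, 39L),
    end = c(200L, 230L, 410L, 42L), stringsAsFactors = FALSE)
  list(atoms = atoms, coords = coords, domainMap = domainMap,
       positions = positions)
}

#' Generate the synthetic pore scaffold
#'
#' Builds a three-domain pore scaffold (FeS, Arch, ATPase lobe 1
#' pseudo-clusters carrying the canonical pore residues with Calpha and
#' minimal side-chain pseudo-atoms) threaded by a 4-nt B-form ssDNA
#' track. By construction the Calpha(135)-Calpha(220) pore width and
#' the closest approach between the residue-380 side chain and
#' residues 219/220 equal the requested values exactly.
#'
#' @param lesion build the tandem-lesion (T64) strand variant
#' @param poreWidth planted pore width, Angstrom
#' @param minGap planted closest approach, Angstrom
#' @return list(topology = Topology, reference = n x 3 coords)
#' @export
generateScaffold <- function(lesion = FALSE, poreWidth = 16.7,
                             minGap = 2.8) {
  sc <- .buildScaffold(lesion = lesion, poreWidth = poreWidth,
                       minGap = minGap)
  topo <- makeTopology(sc$atoms, domainMap = sc$domainMap,
                       positions = sc$positions)
  list(topology = topo, reference = unname(sc$coords))
}

#' Scenario specification for the trajectory generator
#'
#' @param kind scenario class; determines the default event schedule
#'   and the ground-truth label
#' @param nFrames number of frames (>= 2)
#' @param frameIntervalNs frame spacing, ns
#' @param noiseSigma Gaussian positional noise SD per coordinate,
#'   Angstrom
#' @param seed RNG seed; the output is bit-identical for equal seeds
#' @param eventSchedule list of list(time, event, ...) entries; NULL
#'   uses the default for \code{kind}. Event types: "hop" (position-1
#'   P moves bdnaSpacing along the strand axis), "flip" (position-1
#'   base centroid moves into the pore prism), "open"/"close" (lobe-1
#'   cluster translates +-openShift along the width axis),
#'   "contact_on"/"contact_off" (residue side chain moves to/from
#'   contact with a nucleotide; args residue, nucleotide)
#' @param transitionFrames frames over which an event interpolates
#'   linearly
#' @param plantedHbonds data.frame(donorResno, donorName,
#'   acceptorResno, acceptorName, prob): explicit donor hydrogens are
#'   generated whose placement satisfies each pair with its planted
#'   probability; NULL plants the two anchor pairs (196->dT2 phosphate
#'   0.9, 192->dA0 sugar 0.8)
#' @param lesion use the lesion strand variant
#' @param bdnaSpacing backbone hop length, Angstrom
#' @param openShift pore-opening translation, Angstrom
#' @return list of class "ScenarioSpec"
#' @export
scenarioSpec <- function(kind = c("backbone_translocation", "base_flip",
                                  "entrapment", "pore_open_close",
                                  "custom"),
                         nFrames = 150, frameIntervalNs = 10,
                         noiseSigma = 0.5, seed = 1,
                         eventSchedule = NULL, transitionFrames = 50,
                         plantedHbonds = NULL, lesion = FALSE,
                         bdnaSpacing = 7.0, openShift = 3.6) {
  kind <- match.arg(kind)
  stopifnot(nFrames >= 2, noiseSigma >= 0, transitionFrames >= 1)
  if (is.null(eventSchedule)) {
    ## default onset at 400 ns, pulled in for short trajectories
    t0 <- min(400, round(0.4 * (nFrames - 1) * frameIntervalNs))
    eventSchedule <- switch(kind,
      backbone_translocation = list(list(time = t0, event = "hop")),
      base_flip = list(list(time = t0, event = "flip")),
      pore_open_close = list(list(time = t0, event = "open")),
      entrapment = list(),
      custom = list())
  }
  if (is.null(plantedHbonds)) {
    plantedHbonds <- data.frame(
      donorResno = c(196L, 192L), donorName = c("NH1", "OH"),
      acceptorResno = c(41L, 39L), acceptorName = c("OP1", "O4'"),
      prob = c(0.9, 0.8))
    ## the lesion strand has no position-2 phosphate; keep the intact
    ## sugar-anchor pair only
    if (lesion) plantedHbonds <- plantedHbonds[2, , drop = FALSE]
  }
  tmax <- (nFrames - 1) * frameIntervalNs
  for (ev in eventSchedule)
    if (ev$time < 0 || ev$time > tmax)
      stop("event time ", ev$time, " outside the trajectory (0..",
           tmax, " ns)")
  stopifnot(all(plantedHbonds$prob >= 0 & plantedHbonds$prob <= 1))
  structure(list(kind = kind, nFrames = as.integer(nFrames),
                 frameIntervalNs = frameIntervalNs,
                 noiseSigma = noiseSigma, seed = as.integer(seed),
                 eventSchedule = eventSchedule,
                 transitionFrames = as.integer(transitionFrames),
                 plantedHbonds = plantedHbonds, lesion = lesion,
                 bdnaSpacing = bdnaSpacing, openShift = openShift),
            class = "ScenarioSpec")
}

.findAtom <- function(topology, resno, name) {
  i <- which(topology@atoms$resno == resno & topology@atoms$name == name)
  if (length(i) != 1L)
    stop("cannot locate atom ", name, " of residue ", resno)
  i
}

## Resolve an event into (atom indices, full displacement vector)
.resolveEvent <- function(ev, topo, ref, spec, config = poreConfig()) {
  a <- topo@atoms
  pos1 <- topo@positions[["1"]]
  switch(ev$event,
    hop = {
      idx <- which(a$resno == pos1 & a$chain == "D" &
                   a$name %in% c("P", "OP1", "OP2"))
      list(atoms = idx, delta = c(0, 0, spec$bdnaSpacing))
    },
    flip = {
      baseIdx <- which(a$resno == pos1 & a$chain == "D" &
                       a$name %in% c(.BASE_ATOMS, "C7"))
      anchors <- .prismAnchorPoints(topo, ref, config)
      target <- colMeans(anchors)
      cen <- colMeans(ref[baseIdx, , drop = FALSE])
      list(atoms = baseIdx, delta = target - cen)
    },
    open = ,
    close = {
      idx <- which(a$chain == "A" & a$resno >= 215 & a$resno <= 221)
      u <- .unit(ref[.findAtom(topo, 220, "CA"), ] -
                 ref[.findAtom(topo, 135, "CA"), ])
      s <- if (ev$event == "open") spec$openShift else -spec$openShift
      list(atoms = idx, delta = s * u)
    },
    contact_on = ,
    contact_off = {
      sc <- which(a$resno == ev$residue & a$chain == "A" &
                  !(a$name %in% .PROT_BB) & a$element != "H")
      nuc <- which(a$resno == ev$nucleotide & a$chain == "D" &
                   a$element != "H")
      scCen <- colMeans(ref[sc, , drop = FALSE])
      nucCen <- colMeans(ref[nuc, , drop = FALSE])
      d <- sqrt(sum((nucCen - scCen)^2))
      delta <- (1 - 3.0 / d) * (nucCen - scCen)
      if (ev$event == "contact_off") delta <- -delta
      list(atoms = sc, delta = delta)
    },
    stop("unknown event type: ", ev$event))
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Deterministic given the seed. Events displace their atoms along a
#' linear interpolation over \code{transitionFrames} frames; planted
#' hydrogen-bond pairs get an explicit donor hydrogen whose per-frame
#' placement satisfies the geometric criterion with exactly the
#' planted probability; independent Gaussian noise of SD
#' \code{noiseSigma} is added per coordinate and frame (the planted
#' pairs' donor/acceptor heavy atoms are pinned so the Bernoulli
#' outcome is exact).
#'
#' @param spec a \code{\link{scenarioSpec}}
#' @return list(trajectory = Trajectory, truth = ground-truth list,
#'   reference = reference frame coords)
#' @export
generateTrajectory <- function(spec) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  sc <- generateScaffold(lesion = spec$lesion)
  topo <- sc$topology; ref <- sc$reference
  a <- topo@atoms

  events <- lapply(spec$eventSchedule, .resolveEvent, topo = topo,
                   ref = ref, spec = spec)
  times <- (seq_len(spec$nFrames) - 1) * spec$frameIntervalNs
  evStart <- vapply(spec$eventSchedule, function(e)
    which.min(abs(times - e$time)), 0L)
  ## concurrent events may not move the same atoms
  if (length(events) > 1L) {
    for (i in seq_along(events)[-1L]) for (j in seq_len(i - 1L)) {
      overlapT <- abs(evStart[i] - evStart[j]) < spec$transitionFrames
      overlapA <- length(intersect(events[[i]]$atoms,
                                   events[[j]]$atoms)) > 0L
      if (overlapT && overlapA)
        stop("schedule conflict: two concurrent events move the same atoms")
    }
  }

  ## planted H-bond machinery: add explicit hydrogens to the topology
  hb <- spec$plantedHbonds
  nPairs <- nrow(hb)
  dIdx <- aIdx <- integer(nPairs)
  if (nPairs) {
    for (p in seq_len(nPairs)) {
      dIdx[p] <- .findAtom(topo, hb$donorResno[p], hb$donorName[p])
      aIdx[p] <- .findAtom(topo, hb$acceptorResno[p], hb$acceptorName[p])
    }
    hAtoms <- data.frame(
      name = sprintf("H%02d", seq_len(nPairs)),
      resname = a$resname[dIdx], resno = a$resno[dIdx],
      chain = a$chain[dIdx], element = "H", stringsAsFactors = FALSE)
    atoms2 <- rbind(a[, c("name", "resname", "resno", "chain",
                          "element")], hAtoms)
    refH <- t(vapply(seq_len(nPairs), function(p)
      ref[dIdx[p], ] + 1.0 * .unit(ref[aIdx[p], ] - ref[dIdx[p], ]),
      numeric(3)))
    ref2 <- rbind(ref, refH)
    ## keep residues blocked together so hydrogen assignment works
    ord <- order(match(atoms2$chain, c("A", "D")), atoms2$resno,
                 seq_len(nrow(atoms2)))
    atoms2 <- atoms2[ord, ]; ref2 <- ref2[ord, , drop = FALSE]
    topo <- makeTopology(atoms2, domainMap = topo@domainMap,
                         positions = topo@positions)
    ## re-locate indices after reordering
    remap <- ord
    inv <- integer(length(remap)); inv[remap] <- seq_along(remap)
    dIdx <- inv[dIdx]; aIdx <- inv[aIdx]
    hIdx <- inv[nrow(a) + seq_len(nPairs)]
    events <- lapply(events, function(e) {
      e$atoms <- inv[e$atoms]; e
    })
    ref <- ref2
  } else hIdx <- integer()

  n <- nrow(topo@atoms)
  pinned <- unique(c(dIdx, aIdx, hIdx))
  coords <- array(NA_real_, dim = c(n, 3L, spec$nFrames))
  set.seed(spec$seed)
  for (f in seq_len(spec$nFrames)) {
    m <- ref
    for (k in seq_along(events)) {
      ramp <- (f - evStart[k] + 1) / spec$transitionFrames
      ramp <- min(max(ramp, 0), 1)
      if (ramp > 0)
        m[events[[k]]$atoms, ] <-
          m[events[[k]]$atoms, , drop = FALSE] +
          matrix(events[[k]]$delta, length(events[[k]]$atoms), 3,
                 byrow = TRUE) * ramp
    }
    noise <- matrix(stats::rnorm(n * 3L, 0, spec$noiseSigma), n, 3L)
    if (length(pinned)) noise[pinned, ] <- 0
    m <- m + noise
    ## encode each pair's Bernoulli outcome in the donor-H placement
    for (p in seq_len(nPairs)) {
      hit <- stats::runif(1) < hb$prob[p]
      dv <- .unit(m[aIdx[p], ] - m[dIdx[p], ])
      hpos <- if (hit) m[dIdx[p], ] + 1.0 * dv
              else m[dIdx[p], ] + 1.0 * .unit(.cross3(dv, c(0, 0, 1)))
      m[hIdx[p], ] <- hpos
    }
    coords[, , f] <- m
  }
  traj <- makeTrajectory(topo, coords, times = times)
  label <- switch(spec$kind,
    backbone_translocation = "backbone_translocation",
    base_flip = "base_translocation",
    entrapment = , pore_open_close = , custom = "blocked")
  truth <- list(
    kind = spec$kind, label = label, seed = spec$seed,
    eventTimes = vapply(spec$eventSchedule, `[[`, numeric(1), "time"),
    eventTypes = vapply(spec$eventSchedule, `[[`, character(1), "event"),
    pDisplacement = if (spec$kind == "backbone_translocation")
      spec$bdnaSpacing else 0,
    occupancies = hb, noiseSigma = spec$noiseSigma,
    poreWidth = 16.7, minGap = 2.8,
    transitionNs = spec$transitionFrames * spec$frameIntervalNs)
  list(trajectory = traj, truth = truth, reference = ref)
}

#' Default 30-replica fixture specification set
#'
#' Ten replicas per planted class (backbone translocation, base flip,
#' entrapment) with seeds 1..30, mirroring a replica-population design.
#'
#' @param noiseSigma positional noise SD, Angstrom
#' @param nFrames frames per replica
#' @return list of \code{\link{scenarioSpec}} objects
#' @export
defaultFixtureSpecs <- function(noiseSigma = 0.5, nFrames = 150) {
  kinds <- rep(c("backbone_translocation", "base_flip", "entrapment"),
               each = 10)
  lapply(seq_along(kinds), function(i)
    scenarioSpec(kind = kinds[i], seed = i, noiseSigma = noiseSigma,
                 nFrames = nFrames))
}

#' Write a fixture set to disk
#'
#' Each scenario is written as a multi-model PDB and an XYZ file plus a
#' JSON ground-truth file; a manifest JSON indexes the set.
#'
#' @param specs list of \code{\link{scenarioSpec}}; NULL uses
#'   \code{\link{defaultFixtureSpecs}}
#' @param outDir output directory (created if missing)
#' @return invisible manifest path
#' @export
writeFixtureSet <- function(specs = NULL, outDir) {
  if (is.null(specs)) specs <- defaultFixtureSpecs()
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(specs)) {
    g <- generateTrajectory(specs[[i]])
    stem <- sprintf("scenario_%02d_%s", i, specs[[i]]$kind)
    pdb <- file.path(outDir, paste0(stem, ".pdb"))
    xyz <- file.path(outDir, paste0(stem, ".xyz"))
    tr <- file.path(outDir, paste0(stem, "_truth.json"))
    writeTrajectoryPDB(g$trajectory, pdb)
    writeTrajectoryXYZ(g$trajectory, xyz)
    jsonlite::write_json(g$truth, tr, auto_unbox = TRUE, digits = NA)
    entries[[i]] <- list(stem = stem, pdb = basename(pdb),
                         xyz = basename(xyz), truth = basename(tr),
                         kind = specs[[i]]$kind,
                         label = g$truth$label,
                         seed = specs[[i]]$seed,
                         nAtoms = nAtoms(g$trajectory),
                         nFrames = nFrames(g$trajectory))
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(list(count = length(entries), entries = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
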