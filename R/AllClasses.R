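#' @import methods
NULL

## Residue-name vocabularies used throughout. T64 is the tandem-lesion
## residue: two crosslinked thymine rings carried as one residue whose
## atom names are prefixed "5" (5' ring) or "3" (3' ring).
.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
             "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
             "THR", "TRP", "TYR", "VAL")
.NUC3 <- c("DA", "DT", "DG", "DC", "DA5", "DT5", "DG5", "DC5",
           "DA3", "DT3", "DG3", "DC3", "A", "T", "G", "C", "U", "DU",
           "T64")
.LESION_RES <- "T64"
.DOMAINS <- c("FeS", "Arch", "ATPase1", "ATPase2", "DNA")
.LABELS <- c("backbone_translocation", "base_translocation", "blocked")

#' Topology of a pore-ssDNA system
#'
#' Ordered atom records plus domain annotation for a helicase-ssDNA
#' complex. Atom ids are contiguous from 0 in file order; atom positions
#' used by selection and geometry functions are 1-based row positions
#' into the atom table.
#'
#' @slot atoms data.frame with columns \code{id} (0-based, contiguous),
#'   \code{name}, \code{element}, \code{resname}, \code{resno},
#'   \code{chain}.
#' @slot domainMap data.frame with columns \code{domain} (one of FeS,
#'   Arch, ATPase1, ATPase2, DNA), \code{chain}, \code{start},
#'   \code{end} (inclusive residue-number range).
#' @slot lesionResidues integer residue numbers flagged as chemically
#'   modified (the tandem pyrimidine-pyrimidone lesion).
#' @slot positions named integer; optional map of nucleotide position
#'   labels ("0".."3") to residue numbers.
#' @export
setClass("Topology",
  representation(atoms = "data.frame", domainMap = "data.frame",
                 lesionResidues = "integer", positions = "integer"),
  prototype(atoms = data.frame(), domainMap = data.frame(
    domain = character(), chain = character(),
    start = integer(), end = integer()),
    lesionResidues = integer(), positions = integer()))

setValidity("Topology", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("id", "name", "element", "resname", "resno", "chain")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (!identical(as.integer(a$id), seq_len(nrow(a)) - 1L))
      msgs <- c(msgs, "atom ids must be unique and contiguous from 0")
    ## each residue (chain, resno) must sit in exactly one chain: by key
    ## construction a residue is (chain, resno); check resno not reused
    ## with conflicting resname inside one chain
    key <- paste(a$chain, a$resno)
    rn <- tapply(a$resname, key, function(x) length(unique(x)))
    if (any(rn > 1L))
      msgs <- c(msgs, "a residue number maps to multiple residue names within one chain")
    ## DNA residues: exactly one P except a 5' terminus
    dna <- a[a$resname %in% .NUC3, , drop = FALSE]
    if (nrow(dna)) {
      for (ch in unique(dna$chain)) {
        d <- dna[dna$chain == ch, , drop = FALSE]
        resn <- sort(unique(d$resno))
        np <- vapply(resn, function(r) sum(d$name[d$resno == r] == "P"), 0L)
        if (any(np > 1L))
          msgs <- c(msgs, "a DNA residue has more than one P atom")
        if (sum(np == 0L) > 1L)
          msgs <- c(msgs, "more than one DNA residue lacks a P atom (only the 5' terminus may)")
      }
    }
  }
  dm <- object@domainMap
  if (nrow(dm)) {
    if (!all(dm$domain %in% .DOMAINS))
      msgs <- c(msgs, paste("domain tags must be in:", paste(.DOMAINS, collapse = ", ")))
    ## non-overlapping ranges within a chain
    for (ch in unique(dm$chain)) {
      d <- dm[dm$chain == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
        msgs <- c(msgs, "domain residue ranges overlap")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory of a pore-ssDNA system
#'
#' Per-frame coordinates (Angstrom) over a strictly increasing time base
#' (ns), bound to the Topology they instantiate.
#'
#' @slot topology a \linkS4class{Topology}.
#' @slot coords numeric array with dim (n_atoms, 3, n_frames), Angstrom.
#' @slot times numeric vector of frame times in ns, strictly increasing.
#' @export
setClass("Trajectory",
  representation(topology = "Topology", coords = "array",
                 times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an (n_atoms, 3, n_frames) array")
  if (d[3] < 1L) msgs <- c(msgs, "at least one frame is required")
  if (d[1] != nrow(object@topology@atoms))
    msgs <- c(msgs, sprintf("coords have %d atoms but topology has %d",
                            d[1], nrow(object@topology@atoms)))
  tt <- object@times
  if (length(tt) != d[3])
    msgs <- c(msgs, "times length must equal frame count")
  if (length(tt) > 1L && any(diff(tt) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Rigid-body transform from a least-squares superposition
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation vector (Angstrom). The
#'   transform maps x to rotation %*% x + translation.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation must be a proper rotation (det = +1 within 1e-6)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  TRUE
})

#' Per-replica translocation analysis report
#'
#' Aggregates the observables of one replica: pore geometry statistics,
#' equilibration window, per-nucleotide displacement tracks, stage
#' segmentation, behavior label, representative frame and bend metric.
#' Losslessly serializable to JSON via \code{\link{writeReport}}.
#'
#' @slot replicaId character scalar.
#' @slot poreStats named list of \code{SeriesStat}-style lists for the
#'   width, gap and minimum-gap series.
#' @slot window numeric length 2, (t_start, t_end) in ns.
#' @slot tracks named list of nucleotide tracks (see
#'   \code{\link{nucleotideTrack}}).
#' @slot stages stage segmentation (see \code{\link{segmentStages}}).
#' @slot label behavior label with evidence (see
#'   \code{\link{classifyBehavior}}).
#' @slot representative integer frame index of the ensemble medoid.
#' @slot bendStats list; windowed bend statistics, possibly empty.
#' @slot version character schema version.
#' @export
setClass("TranslocationReport",
  representation(replicaId = "character", poreStats = "list",
                 window = "numeric", tracks = "list", stages = "list",
                 label = "list", representative = "integer",
                 bendStats = "list", version = "character"),
  prototype(version = "1.0"))

setValidity("TranslocationReport", function(object) {
  if (length(object@window) && length(object@window) != 2L)
    return("window must have length 2")
  if (length(object@label) &&
      !identical(sort(c("label", "evidence") %in% names(object@label)),
                 c(TRUE, TRUE)))
    return("label must carry 'label' and 'evidence'")
  if (length(object@label) && !(object@label$label %in% .LABELS))
    return(paste("label must be one of:", paste(.LABELS, collapse = ", ")))
  TRUE
})
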