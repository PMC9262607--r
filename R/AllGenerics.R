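#' Number of atoms
#' @param x a Topology or Trajectory
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a Trajectory
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom table accessor
#' @param x a Topology or Trajectory
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Domain map accessor
#' @param x a Topology or Trajectory
#' @export
setGeneric("domainMap", function(x) standardGeneric("domainMap"))

#' Frame times (ns) accessor
#' @param x a Trajectory
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' Coordinates of one frame
#' @param x a Trajectory
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix, Angstrom
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' Topology accessor
#' @param x a Trajectory
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname nAtoms
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname nAtoms
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname nFrames
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname atomTable
setMethod("atomTable", "Topology", function(x) x@atoms)
#' @rdname atomTable
setMethod("atomTable", "Trajectory", function(x) x@topology@atoms)
#' @rdname domainMap
setMethod("domainMap", "Topology", function(x) x@domainMap)
#' @rdname domainMap
setMethod("domainMap", "Trajectory", function(x) x@topology@domainMap)
#' @rdname trajTimes
setMethod("trajTimes", "Trajectory", function(x) x@times)
#' @rdname topology
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname frameCoords
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              length(unique(a$chain))))
  if (nrow(object@domainMap)) {
    cat("  domains:",
        paste(sprintf("%s[%d-%d]", object@domainMap$domain,
                      object@domainMap$start, object@domainMap$end),
              collapse = " "), "\n")
  }
  if (length(object@lesionResidues))
    cat("  lesion residue(s):",
        paste(object@lesionResidues, collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  tt <- object@times
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.3f..%.3f ns\n",
              nFrames(object), nAtoms(object), tt[1], tt[length(tt)]))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (x -> R x + t)\n")
  cat("  rotation angle:",
      sprintf("%.3f deg", acos(pmin(1, pmax(-1,
        (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi), "\n")
  cat("  translation:",
      sprintf("(%.3f, %.3f, %.3f) A", object@translation[1],
              object@translation[2], object@translation[3]), "\n")
})

setMethod("show", "TranslocationReport", function(object) {
  cat("TranslocationReport", object@replicaId, "\n")
  if (length(object@window))
    cat(sprintf("  window: %.1f-%.1f ns\n", object@window[1],
                object@window[2]))
  if (length(object@label))
    cat("  behavior:", object@label$label, "\n")
  if (length(object@representative))
    cat("  representative frame:", object@representative, "\n")
})
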