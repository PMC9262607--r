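## Report assembly and lossless JSON (de)serialization.

.seriesToList <- function(s) list(time_ns = s$time_ns, value = s$value)
.seriesFromList <- function(l)
  data.frame(time_ns = as.numeric(l$time_ns), value = as.numeric(l$value))

.trackToList <- function(tr) {
  list(nucleotide = tr$nucleotide,
       pDisplacement = if (is.null(tr$pDisplacement)) NULL
                       else .seriesToList(tr$pDisplacement),
       heavyRmsd = .seriesToList(tr$heavyRmsd),
       baseCentroids = tr$baseCentroids)
}
.trackFromList <- function(l) {
  structure(list(
    nucleotide = as.integer(l$nucleotide),
    pDisplacement = if (is.null(l$pDisplacement)) NULL
                    else .seriesFromList(l$pDisplacement),
    heavyRmsd = .seriesFromList(l$heavyRmsd),
    baseCentroids = if (is.null(l$baseCentroids)) NULL
                    else matrix(unlist(l$baseCentroids), ncol = 3,
                                byrow = TRUE)),
    class = "NucleotideTrack")
}

#' Assemble a TranslocationReport
#' @param replicaId character id
#' @param poreStats named list of seriesStat results
#' @param window numeric length 2 (ns)
#' @param tracks named list of nucleotide tracks
#' @param stages a StageSegmentation (or empty list)
#' @param label a classifyBehavior result
#' @param representative medoid frame index
#' @param bendStats list (possibly empty)
#' @return a \linkS4class{TranslocationReport}
#' @export
translocationReport <- function(replicaId, poreStats, window, tracks,
                                stages, label, representative,
                                bendStats = list()) {
  new("TranslocationReport", replicaId = as.character(replicaId),
      poreStats = poreStats, window = as.numeric(window),
      tracks = tracks, stages = unclass(stages), label = label,
      representative = as.integer(representative),
      bendStats = bendStats)
}

#' Write a TranslocationReport as JSON
#'
#' The serialization is lossless and deterministic (no timestamps);
#' \code{\link{readReport}} restores an equal object.
#'
#' @param report a \linkS4class{TranslocationReport}
#' @param path output path
#' @export
writeReport <- function(report, path) {
  stages <- report@stages
  if (length(stages) && !is.null(stages$fingerprints)) {
    fp <- stages$fingerprints
    stages$fingerprints <- list(values = as.integer(fp),
                                nrow = nrow(fp),
                                labels = colnames(fp))
  }
  obj <- list(schema = "poretrack-report",
              version = report@version,
              replicaId = report@replicaId,
              poreStats = report@poreStats,
              window = report@window,
              tracks = lapply(report@tracks, .trackToList),
              stages = stages,
              label = report@label,
              representative = report@representative,
              bendStats = report@bendStats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a TranslocationReport from JSON
#' @param path JSON path written by \code{\link{writeReport}}
#' @return a \linkS4class{TranslocationReport}
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$schema, "poretrack-report"))
    stop("not a report file: ", path)
  stages <- obj$stages
  if (length(stages) && !is.null(stages$fingerprints)) {
    f <- stages$fingerprints
    m <- matrix(as.integer(unlist(f$values)), nrow = f$nrow)
    colnames(m) <- unlist(f$labels)
    stages$fingerprints <- m
    stages$boundaries <- as.numeric(unlist(stages$boundaries))
    stages$stages <- data.frame(
      start = vapply(stages$stages, function(r) as.numeric(r$start),
                     numeric(1)),
      end = vapply(stages$stages, function(r) as.numeric(r$end),
                   numeric(1)))
  }
  ev <- obj$label$evidence
  ev <- lapply(ev, function(x) if (is.list(x)) unlist(x) else x)
  new("TranslocationReport",
      replicaId = obj$replicaId,
      poreStats = lapply(obj$poreStats, function(s)
        list(mean = s$mean, sd = s$sd,
             window = as.numeric(unlist(s$window)),
             nFrames = as.integer(s$nFrames))),
      window = as.numeric(unlist(obj$window)),
      tracks = lapply(obj$tracks, .trackFromList),
      stages = if (is.null(stages)) list() else stages,
      label = list(label = obj$label$label, evidence = ev),
      representative = as.integer(obj$representative),
      bendStats = if (is.null(obj$bendStats)) list() else obj$bendStats,
      version = obj$version)
}
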