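## Structure / trajectory I/O. PDB reading is delegated to bio3d; the
## multi-model PDB writer and the XYZ fixture format are implemented
## here. All coordinates are Angstrom; all times are ns.

.inferElement <- function(name) {
  ## strip leading digits/primes, take leading letters; two-letter
  ## elements are not expected among the pseudo-atoms handled here
  core <- sub("^[0-9']+", "", name)
  el <- toupper(substr(core, 1L, 1L))
  el[!nzchar(el)] <- ""
  el
}

#' Construct a Topology
#'
#' @param atoms data.frame with at least \code{name}, \code{resname},
#'   \code{resno}, \code{chain}; \code{element} is inferred from the
#'   atom name when absent; \code{id} is assigned 0..n-1 in row order.
#' @param domainMap data.frame(domain, chain, start, end) or NULL.
#' @param lesionResidues integer residue numbers of modified residues;
#'   by default residues named \code{T64}.
#' @param positions named integer mapping nucleotide position labels to
#'   residue numbers (e.g. c("0" = 39, "1" = 40)).
#' @return a \linkS4class{Topology}
#' @export
makeTopology <- function(atoms, domainMap = NULL, lesionResidues = NULL,
                         positions = integer()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element)) atoms$element <- .inferElement(atoms$name)
  atoms$element[is.na(atoms$element)] <- ""
  atoms$id <- seq_len(nrow(atoms)) - 1L
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c("id", "name", "element", "resname", "resno", "chain")]
  if (is.null(domainMap))
    domainMap <- data.frame(domain = character(), chain = character(),
                            start = integer(), end = integer(),
                            stringsAsFactors = FALSE)
  if (is.null(lesionResidues))
    lesionResidues <- sort(unique(atoms$resno[atoms$resname %in% .LESION_RES]))
  new("Topology", atoms = atoms, domainMap = as.data.frame(domainMap),
      lesionResidues = as.integer(lesionResidues),
      positions = structure(as.integer(positions),
                            names = names(positions)))
}

#' Construct a Trajectory
#'
#' @param topology a \linkS4class{Topology}
#' @param coords (n_atoms, 3, n_frames) array, or an n_atoms x 3 matrix
#'   for a single frame, Angstrom.
#' @param times frame times in ns; synthesized as 0, interval, ... when
#'   NULL.
#' @param frameIntervalNs frame spacing used when \code{times} is NULL.
#' @return a \linkS4class{Trajectory}
#' @export
makeTrajectory <- function(topology, coords, times = NULL,
                           frameIntervalNs = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * frameIntervalNs
  new("Trajectory", topology = topology, coords = coords,
      times = as.numeric(times))
}

## ---- PDB ------------------------------------------------------------

.validatePDBLines <- function(lines) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in sel) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM/HETATM record at line %d: too short", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop(sprintf("malformed ATOM/HETATM record at line %d: non-numeric coordinates", i))
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop(sprintf("malformed ATOM/HETATM record at line %d: bad residue number", i))
  }
  ## duplicate atom serials within one model
  model <- cumsum(rec == "MODEL ")
  if (length(sel)) {
    ser <- suppressWarnings(as.integer(substr(lines[sel], 7, 11)))
    key <- split(ser, model[sel])
    for (k in key)
      if (anyDuplicated(k[!is.na(k)]))
        stop("duplicate atom id in PDB model")
  }
  invisible(TRUE)
}

#' Load a structure from a PDB file
#'
#' Reads a (possibly multi-model) PDB coordinate file into a Topology
#' plus Trajectory. Atom order equals file order. Multi-model files
#' yield multi-frame trajectories with synthetic times 0, 1, 2, ... ns
#' unless \code{frameIntervalNs} overrides the spacing.
#'
#' @param path PDB file path.
#' @param domainMap optional domain annotation (see
#'   \code{\link{makeTopology}}).
#' @param frameIntervalNs synthetic frame spacing in ns.
#' @return list(topology = Topology, trajectory = Trajectory)
#' @export
loadStructure <- function(path, domainMap = NULL, frameIntervalNs = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  .validatePDBLines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  el[is.na(el) | !nzchar(trimws(el))] <- ""
  el <- trimws(el)
  miss <- !nzchar(el)
  el[miss] <- .inferElement(trimws(a$elety[miss]))
  atoms <- data.frame(name = trimws(a$elety), element = el,
                      resname = trimws(a$resid), resno = a$resno,
                      chain = ifelse(is.na(a$chain), " ", a$chain),
                      stringsAsFactors = FALSE)
  topo <- makeTopology(atoms, domainMap = domainMap)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(topology = topo,
       trajectory = makeTrajectory(topo, coords,
                                   frameIntervalNs = frameIntervalNs))
}

#' Write a (multi-model) PDB file
#'
#' @param trajectory a Trajectory (each frame becomes one MODEL).
#' @param path output path.
#' @export
writeTrajectoryPDB <- function(trajectory, path) {
  a <- atomTable(trajectory)
  nf <- nFrames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  fmtName <- function(nm) {
    ## PDB column alignment: 1-3 char names start in column 14
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  nms <- fmtName(a$name)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frameCoords(trajectory, f)
    writeLines(sprintf(
      "ATOM  %5d %s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (a$id %% 99999L) + 1L, nms, " ", substr(a$resname, 1, 4), a$chain,
      a$resno, m[, 1], m[, 2], m[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- XYZ (fixture format) -------------------------------------------

#' Write a trajectory in XYZ format
#'
#' Plain multi-frame XYZ: per frame an atom count line, a comment line
#' carrying \code{t= <ns>}, then one \code{name x y z} line per atom.
#'
#' @param trajectory a Trajectory
#' @param path output path
#' @export
writeTrajectoryXYZ <- function(trajectory, path) {
  a <- atomTable(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(trajectory))) {
    m <- frameCoords(trajectory, f)
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("t= %.6f", trajTimes(trajectory)[f]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", a$name,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

.readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    cm <- lines[i + 1L]
    tm <- regmatches(cm, regexpr("t=\\s*[-0-9.eE+]+", cm))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  list(coords = frames, times = times)
}

## ---- AMBER NetCDF ---------------------------------------------------

.readNetCDF <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading AMBER NetCDF trajectories requires the ncdf4 package")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  xyz <- ncdf4::ncvar_get(nc, "coordinates") # (3, atoms, frames)
  tm <- tryCatch(as.numeric(ncdf4::ncvar_get(nc, "time")) / 1000,
                 error = function(e) NULL)  # ps -> ns
  if (length(dim(xyz)) == 2L) dim(xyz) <- c(dim(xyz), 1L)
  nf <- dim(xyz)[3]
  frames <- lapply(seq_len(nf), function(f) t(xyz[, , f]))
  list(coords = frames,
       times = if (is.null(tm)) rep(NA_real_, nf) else tm)
}

.sniffFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "xyz") return("xyz")
  if (ext %in% c("nc", "ncdf", "netcdf", "mdcrd")) return("netcdf")
  head <- readBin(path, "raw", n = 4L)
  if (length(head) >= 3L && rawToChar(head[1:3]) == "CDF") return("netcdf")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST)", first)) return("pdb")
  if (grepl("^\\s*[0-9]+\\s*$", first)) return("xyz")
  stop("unrecognized trajectory format for ", path,
       " (detected neither PDB, XYZ nor NetCDF)")
}

#' Load trajectory frames onto an existing topology
#'
#' Supported formats: multi-model PDB, plain XYZ, and AMBER NetCDF
#' (requires the ncdf4 package). Frames from multiple files are
#' concatenated in path order. Times are read from the file when
#' present, otherwise synthesized from \code{frameIntervalNs}.
#'
#' @param topology a \linkS4class{Topology}
#' @param paths character vector of trajectory files
#' @param frameIntervalNs frame spacing for synthesized times (ns)
#' @return a \linkS4class{Trajectory}
#' @export
loadTrajectory <- function(topology, paths, frameIntervalNs = 1) {
  frames <- list(); times <- numeric()
  for (p in paths) {
    if (!file.exists(p)) stop("no such file: ", p)
    fmt <- .sniffFormat(p)
    got <- switch(fmt,
      pdb = {
        s <- loadStructure(p)
        tr <- s$trajectory
        list(coords = lapply(seq_len(nFrames(tr)),
                             function(f) frameCoords(tr, f)),
             times = rep(NA_real_, nFrames(tr)))
      },
      xyz = .readXYZ(p),
      netcdf = .readNetCDF(p))
    nat <- vapply(got$coords, nrow, 0L)
    if (any(nat != nAtoms(topology)))
      stop(sprintf("atom-count mismatch: trajectory '%s' has %d atoms, topology has %d",
                   p, nat[which(nat != nAtoms(topology))[1]],
                   nAtoms(topology)))
    frames <- c(frames, got$coords)
    times <- c(times, got$times)
  }
  if (anyNA(times))
    times <- (seq_along(frames) - 1) * frameIntervalNs
  coords <- array(NA_real_, dim = c(nAtoms(topology), 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  makeTrajectory(topology, coords, times = times)
}

#' Write a time series as CSV
#'
#' Columns \code{time_ns,value}; a leading comment line carries the
#' series name and units.
#' @param series data.frame(time_ns, value)
#' @param path output path
#' @param name series name
#' @param units units string
#' @export
writeSeriesCSV <- function(series, path, name = "series", units = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s [%s]", name, units), con)
  writeLines("time_ns,value", con)
  writeLines(sprintf("%.6f,%.6f", series$time_ns, series$value), con)
  invisible(path)
}
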