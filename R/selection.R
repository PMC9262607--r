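## Atom selection mini-language.
##
## Grammar (case-insensitive keywords, whitespace separated):
##   expr    := term ('or' term)*
##   term    := factor ('and' factor)*
##   factor  := 'not' factor | '(' expr ')' | primary
##   primary := 'name' TOK+ | 'resname' TOK+ | 'resid' RANGE+
##            | 'chain' TOK+ | 'domain' TOK+ | 'element' TOK+
##            | 'heavy' | 'hydrogen' | 'calpha' | 'backbone' | 'base'
##            | 'base:5T' | 'base:3T' | 'P' | 'all'
##   RANGE   := INT | INT:INT
## Resolution is deterministic and order-preserving (indices ascend).

.PROT_BB <- c("N", "CA", "C", "O", "OXT")
.DNA_BB <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "C4'",
             "O4'", "C3'", "O3'", "C2'", "C1'")
.BASE_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                 "O2", "O4", "O6", "N2", "N4", "N6", "C7", "C5M")

.tokenizeSel <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  toks
}

.isNucRow <- function(atoms) atoms$resname %in% .NUC3
.isProtRow <- function(atoms) atoms$resname %in% .AMINO3

.selClassMask <- function(atoms, kw) {
  nuc <- .isNucRow(atoms)
  prot <- .isProtRow(atoms)
  switch(kw,
    all = rep(TRUE, nrow(atoms)),
    heavy = {
      unk <- !nzchar(atoms$element)
      if (any(unk))
        warning(sum(unk), " atom(s) with unknown element treated as heavy")
      atoms$element != "H"
    },
    hydrogen = atoms$element == "H",
    calpha = atoms$name == "CA" & prot,
    p = atoms$element == "P",
    backbone = (prot & atoms$name %in% .PROT_BB) |
               (nuc & (atoms$name %in% .DNA_BB |
                       (atoms$resname %in% .LESION_RES &
                        atoms$name %in% .DNA_BB))),
    base = nuc & (atoms$name %in% .BASE_ATOMS |
                  (atoms$resname %in% .LESION_RES &
                   grepl("^[53]", atoms$name))),
    "base:5t" = atoms$resname %in% .LESION_RES & grepl("^5", atoms$name),
    "base:3t" = atoms$resname %in% .LESION_RES & grepl("^3", atoms$name),
    NULL)
}

.parseRanges <- function(toks) {
  out <- integer()
  for (tk in toks) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, ":")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", tk)) {
      out <- c(out, as.integer(tk))
    } else stop("bad residue range token: ", tk)
  }
  out
}

.domainMask <- function(topology, tags) {
  atoms <- topology@atoms
  dm <- topology@domainMap
  mask <- rep(FALSE, nrow(atoms))
  hit <- tolower(dm$domain) %in% tolower(tags)
  if (!any(hit)) stop("no such domain tag(s): ", paste(tags, collapse = ", "))
  for (i in which(hit))
    mask <- mask | (atoms$chain == dm$chain[i] &
                    atoms$resno >= dm$start[i] & atoms$resno <= dm$end[i])
  mask
}

## Recursive-descent evaluator producing a logical mask; clauses with
## zero matches are recorded for the error message.
.selParser <- function(topology, toks) {
  atoms <- topology@atoms
  pos <- 1L
  zeroClauses <- character()
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  isKw <- function(t, kw) !is.na(t) && tolower(t) == kw

  argToks <- function() {
    out <- character()
    while (!is.na(peek()) &&
           !(tolower(peek()) %in% c("and", "or", "not", ")", "name",
                                    "resname", "resid", "chain",
                                    "domain", "element"))) {
      out <- c(out, take())
    }
    if (!length(out)) stop("selection keyword lacks arguments near: ",
                           paste(toks, collapse = " "))
    out
  }
  notePrim <- function(desc, mask) {
    if (!any(mask)) zeroClauses <<- c(zeroClauses, desc)
    mask
  }

  primary <- function() {
    t <- take()
    lt <- tolower(t)
    if (lt %in% c("name", "resname", "chain", "element")) {
      args <- argToks()
      col <- switch(lt, name = atoms$name, resname = atoms$resname,
                    chain = atoms$chain, element = atoms$element)
      notePrim(paste(t, paste(args, collapse = " ")),
               toupper(col) %in% toupper(args))
    } else if (lt == "resid") {
      args <- argToks()
      notePrim(paste(t, paste(args, collapse = " ")),
               atoms$resno %in% .parseRanges(args))
    } else if (lt == "domain") {
      args <- argToks()
      notePrim(paste(t, paste(args, collapse = " ")),
               .domainMask(topology, args))
    } else {
      m <- .selClassMask(atoms, lt)
      if (is.null(m)) stop("unknown selection token: ", t)
      notePrim(t, m)
    }
  }
  factor <- function() {
    t <- peek()
    if (isKw(t, "not")) { take(); return(!factor()) }
    if (isKw(t, "(")) {
      take()
      m <- expr()
      if (!isKw(peek(), ")")) stop("unbalanced parentheses in selection")
      take()
      return(m)
    }
    primary()
  }
  term <- function() {
    m <- factor()
    while (isKw(peek(), "and")) { take(); m <- m & factor() }
    m
  }
  expr <- function() {
    m <- term()
    while (isKw(peek(), "or")) { take(); m <- m | term() }
    m
  }
  mask <- expr()
  if (pos <= length(toks))
    stop("trailing tokens in selection: ",
         paste(toks[pos:length(toks)], collapse = " "))
  list(mask = mask, zero = zeroClauses)
}

#' Resolve an atom selection expression
#'
#' Evaluates a selection expression against a Topology and returns the
#' matching atom positions (1-based row positions into the atom table,
#' sorted ascending). Zero matches are an error naming the clause(s)
#' that matched nothing, never an empty set.
#'
#' @param topology a \linkS4class{Topology}
#' @param expr selection string, e.g. \code{"name CA and resid 135"},
#'   \code{"element P and chain D"}, \code{"heavy and domain FeS"}.
#' @return integer vector of atom positions, ascending.
#' @examples
#' topo <- generateScaffold()$topology
#' resolveSelection(topo, "name CA and resid 135")
#' @export
resolveSelection <- function(topology, expr) {
  stopifnot(is(topology, "Topology"))
  res <- .selParser(topology, .tokenizeSel(expr))
  idx <- which(res$mask)
  if (!length(idx)) {
    hint <- if (length(res$zero))
      paste0(" (unmatched clause: ", paste(unique(res$zero),
                                           collapse = "; "), ")")
    else ""
    stop("selection '", expr, "' matches no atoms", hint)
  }
  idx
}
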