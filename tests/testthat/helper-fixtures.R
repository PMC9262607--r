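## Shared fixtures, built in code at test time.

## A minimal hand-written 3-atom PDB (one water-like fragment).
writeTinyPDB <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  path
}

## Tiny free-floating topology: k atoms on a line, all carbon.
lineTopology <- function(k = 3L) {
  makeTopology(data.frame(
    name = paste0("C", seq_len(k)), resname = "LIG",
    resno = 1L, chain = "X", stringsAsFactors = FALSE))
}

randomRotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),   2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),   a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

## Brute-force exhaustive H-bond evaluation (independent oracle).
bruteForceHBonds <- function(coords, topo, donors, acceptors, crit) {
  a <- topo@atoms
  roles <- hbondRoles(topo)
  donors <- donors[roles$donor[donors]]
  acceptors <- acceptors[roles$acceptor[acceptors]]
  hmap <- PoreTrack:::.assignHydrogens(topo, coords)
  out <- list()
  for (d in donors) for (ac in acceptors) {
    if (d == ac) next
    if (a$chain[d] == a$chain[ac] && a$resno[d] == a$resno[ac]) next
    dd <- sqrt(sum((coords[d, ] - coords[ac, ])^2))
    if (dd > crit$daCutoff) next
    ok <- TRUE
    if (crit$hydrogenMode == "explicit") {
      hs <- as.integer(names(hmap))[!is.na(hmap) & hmap == d]
      if (length(hs)) {
        ang <- vapply(hs, function(h) {
          v1 <- coords[d, ] - coords[h, ]; v2 <- coords[ac, ] - coords[h, ]
          acos(min(1, max(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        }, numeric(1))
        ok <- any(ang >= crit$dhaMinAngle)
      }
    }
    if (ok) out[[length(out) + 1L]] <- c(d, ac)
  }
  if (!length(out)) return(data.frame(donor = integer(),
                                      acceptor = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(donor = m[, 1], acceptor = m[, 2])
  df[order(df$donor, df$acceptor), ]
}

sortPairs <- function(df) {
  df <- df[order(df$donor, df$acceptor), c("donor", "acceptor")]
  rownames(df) <- NULL
  df
}
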