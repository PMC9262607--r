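## A compact donor/acceptor playground: one serine donor (with
## explicit H) facing one backbone carbonyl acceptor.
pairTopo <- function() {
  makeTopology(data.frame(
    name = c("CA", "OG", "HG", "CA", "O"),
    resname = c("SER", "SER", "SER", "ALA", "ALA"),
    resno = c(1L, 1L, 1L, 2L, 2L),
    chain = "A", stringsAsFactors = FALSE))
}

pairCoords <- function(da = 2.9, angle = 160) {
  ## donor OG at origin; acceptor along +x at distance da; H placed so
  ## the D-H...A angle equals `angle`
  th <- (180 - angle) * pi / 180
  h <- c(cos(th), sin(th), 0) * 1.0
  rbind(c(-1.5, 0, 0),      # SER CA
        c(0, 0, 0),         # OG (donor)
        h,                  # HG
        c(da + 1.5, 0, 0),  # ALA CA
        c(da, 0, 0))        # O (acceptor)
}

test_that("the geometric hydrogen-bond criterion gates on distance and angle", {
  topo <- pairTopo()
  don <- 2L; acc <- 5L
  crit <- hbondCriterion(3.5, 135, "explicit")
  hb <- detectHBonds(pairCoords(2.9, 160), topo, don, acc, crit)
  expect_equal(nrow(hb), 1L)
  ## beyond the distance cutoff
  hb <- detectHBonds(pairCoords(3.6, 160), topo, don, acc, crit)
  expect_equal(nrow(hb), 0L)
  ## bad angle
  hb <- detectHBonds(pairCoords(2.9, 90), topo, don, acc, crit)
  expect_equal(nrow(hb), 0L)
  ## inferred mode is distance-only
  hb <- detectHBonds(pairCoords(2.9, 90), topo, don, acc,
                     hbondCriterion(3.5, 135, "inferred"))
  expect_equal(nrow(hb), 1L)
})

test_that("hydrogen-bond detection equals brute-force evaluation on randomized frames", {
  g <- generateTrajectory(scenarioSpec(kind = "entrapment", nFrames = 2,
                                       noiseSigma = 0, seed = 21))
  topo <- topology(g$trajectory)
  roles <- hbondRoles(topo)
  donors <- which(roles$donor)
  acceptors <- which(roles$acceptor)
  crit <- hbondCriterion(3.5, 135, "explicit")
  set.seed(22)
  for (rep in 1:25) {
    ## scatter a random subset of atoms into a tight box to force hits
    m <- frameCoords(g$trajectory, 1)
    idx <- sample(nrow(m), 50)
    m[idx, ] <- matrix(runif(150, 0, 8), 50, 3)
    got <- sortPairs(detectHBonds(m, topo, donors, acceptors, crit))
    want <- sortPairs(bruteForceHBonds(m, topo, donors, acceptors, crit))
    expect_identical(got, want)
  }
})

test_that("planted occupancies are recovered and dead pairs are omitted", {
  spec <- scenarioSpec(kind = "entrapment", nFrames = 2000,
                       frameIntervalNs = 1, noiseSigma = 0, seed = 31,
                       plantedHbonds = data.frame(
                         donorResno = c(196L, 192L),
                         donorName = c("NH1", "OH"),
                         acceptorResno = c(41L, 39L),
                         acceptorName = c("OP1", "O4'"),
                         prob = c(0.75, 0)))
  g <- generateTrajectory(spec)
  topo <- topology(g$trajectory)
  roles <- hbondRoles(topo)
  occ <- hbondOccupancy(g$trajectory, which(roles$donor),
                        which(roles$acceptor))
  a <- atomTable(g$trajectory)
  hot <- occ[a$resno[occ$donor] == 196 & a$name[occ$donor] == "NH1" &
             a$resno[occ$acceptor] == 41 &
             a$name[occ$acceptor] == "OP1", ]
  expect_equal(nrow(hot), 1L)
  expect_lt(abs(hot$occupancy - 0.75), 0.05)
  ## the never-satisfied planted pair is absent
  dead <- occ[a$resno[occ$donor] == 192 & a$name[occ$donor] == "OH" &
              a$resno[occ$acceptor] == 39, ]
  expect_equal(nrow(dead), 0L)
  ## a pair satisfied in every frame has occupancy exactly 1
  spec1 <- scenarioSpec(kind = "entrapment", nFrames = 50,
                        noiseSigma = 0, seed = 32,
                        plantedHbonds = data.frame(
                          donorResno = 196L, donorName = "NH1",
                          acceptorResno = 41L, acceptorName = "OP1",
                          prob = 1))
  g1 <- generateTrajectory(spec1)
  roles1 <- hbondRoles(topology(g1$trajectory))
  occ1 <- hbondOccupancy(g1$trajectory, which(roles1$donor),
                         which(roles1$acceptor))
  a1 <- atomTable(g1$trajectory)
  hot1 <- occ1[a1$resno[occ1$donor] == 196 &
               a1$name[occ1$donor] == "NH1" &
               a1$name[occ1$acceptor] == "OP1", ]
  expect_equal(hot1$occupancy, 1.0)
})

test_that("residue-nucleotide totals sum pair occupancies additively", {
  topo <- generateScaffold()$topology
  a <- atomTable(topo)
  nh1 <- which(a$resno == 196 & a$name == "NH1")
  nh2 <- which(a$resno == 196 & a$name == "NH2")
  ne <- which(a$resno == 196 & a$name == "NE")
  op1 <- which(a$resno == 41 & a$name == "OP1")
  op2 <- which(a$resno == 41 & a$name == "OP2")
  occ <- data.frame(donor = c(nh1, nh2, ne),
                    acceptor = c(op1, op2, op1),
                    occupancy = c(0.9, 0.8, 0.7))
  tot <- totalHBNumber(occ, topo)
  expect_equal(nrow(tot), 1L)
  expect_equal(tot$totalHB, 2.4)
  expect_equal(tot$moiety, "backbone")
  ## single pair passes through unchanged
  tot1 <- totalHBNumber(occ[1, ], topo)
  expect_equal(tot1$totalHB, 0.9)
  ## additivity: splitting and re-summing reproduces the total exactly
  parts <- vapply(1:3, function(i)
    totalHBNumber(occ[i, ], topo)$totalHB, numeric(1))
  expect_identical(sum(parts), tot$totalHB)
  ## base-moiety grouping is separated from the backbone
  o2 <- which(a$resno == 41 & a$name == "O2")
  occ2 <- rbind(occ, data.frame(donor = nh1, acceptor = o2,
                                occupancy = 0.5))
  tot2 <- totalHBNumber(occ2, topo)
  expect_equal(nrow(tot2), 2L)
  expect_setequal(tot2$moiety, c("backbone", "base"))
  ## protein-protein pairs are rejected with the atoms named
  bad <- data.frame(donor = nh1, acceptor = which(a$resno == 219 &
                                                  a$name == "OD1"),
                    occupancy = 0.5)
  expect_error(totalHBNumber(bad, topo), "ARG196")
})

test_that("pi-contact geometry gates on axial position", {
  ## hexagonal ring in the xy plane; probe atom on and off axis
  ring <- cbind(1.39 * cos(seq(0, 5) * pi / 3),
                1.39 * sin(seq(0, 5) * pi / 3), 0)
  topo <- makeTopology(data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CZ", "C7"),
    resname = c(rep("TYR", 6), "ARG", "DT"),
    resno = c(rep(1L, 6), 2L, 3L),
    chain = c(rep("A", 7), "D"), stringsAsFactors = FALSE))
  onAxis <- rbind(ring, c(0, 0, 4), c(0, 0, 4))
  inPlane <- rbind(ring, c(4, 0, 0), c(4, 0, 0))
  tOn <- makeTrajectory(topo, onAxis)
  tIn <- makeTrajectory(topo, inPlane)
  pc <- piContactSeries(tOn, "cation_pi", 7L, 1:6)
  expect_true(pc$satisfied[1])
  expect_equal(pc$fraction, 1)
  expect_false(piContactSeries(tIn, "cation_pi", 7L, 1:6)$satisfied[1])
  ## methyl-pi has the tighter 4.6 A cutoff
  expect_true(piContactSeries(tOn, "methyl_pi", 8L, 1:6)$satisfied[1])
  far <- rbind(ring, c(0, 0, 5), c(0, 0, 5))
  tFar <- makeTrajectory(topo, far)
  expect_true(piContactSeries(tFar, "cation_pi", 7L, 1:6)$satisfied[1])
  expect_false(piContactSeries(tFar, "methyl_pi", 8L, 1:6)$satisfied[1])
  ## role guards
  expect_error(piContactSeries(tOn, "cation_pi", 8L, 1:6), "CZ|NZ")
  expect_error(piContactSeries(tOn, "cation_pi", 7L, 1:3), ">= 5")
})

test_that("random pi placements match a brute-force evaluator", {
  ring <- cbind(1.39 * cos(seq(0, 5) * pi / 3),
                1.39 * sin(seq(0, 5) * pi / 3), 0)
  topo <- makeTopology(data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "NZ"),
    resname = c(rep("TYR", 6), "LYS"),
    resno = c(rep(1L, 6), 2L), chain = "A", stringsAsFactors = FALSE))
  set.seed(33)
  for (rep in 1:500) {
    p <- runif(3, -7, 7)
    m <- rbind(ring, p)
    pc <- piContactSeries(makeTrajectory(topo, m), "cation_pi", 7L, 1:6)
    ## brute force: distance to centroid and angle to the z axis
    d <- sqrt(sum(p^2))
    ang <- acos(abs(p[3]) / d) * 180 / pi
    expect_identical(pc$satisfied[1], d <= 6.0 && ang <= 45)
  }
})

test_that("van-der-Waals contact counts equal brute-force pair enumeration", {
  topo <- lineTopology(20L)
  set.seed(34)
  for (rep in 1:20) {
    m <- matrix(runif(60, 0, 10), 20, 3)
    traj <- makeTrajectory(topo, m)
    A <- 1:10; B <- 11:20
    cnt <- vdwContactSeries(traj, A, B)$value
    brute <- sum(as.matrix(dist(m))[A, B] <= 4.5)
    expect_equal(cnt, brute)
  }
  ## disjoint groups far apart are "abolished"; a fixed 4 A pair counts 1
  m <- matrix(0, 20, 3); m[11:20, 1] <- 20
  tFar <- makeTrajectory(topo, array(rep(m, 2), dim = c(20, 3, 2)))
  s <- vdwContactSeries(tFar, 1:10, 11:20)
  expect_equal(s$value, c(0, 0))
  expect_true(vdwAbolished(s, c(0, 1)))
  m2 <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  t2 <- makeTrajectory(lineTopology(2L),
                       array(rep(m2, 3), dim = c(2, 3, 3)))
  s2 <- vdwContactSeries(t2, 1L, 2L)
  expect_equal(s2$value, rep(1, 3))
  expect_false(vdwAbolished(s2, c(0, 2)))
})
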