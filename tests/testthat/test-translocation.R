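test_that("pore geometry series reproduce the planted noiseless geometry", {
  g <- generateTrajectory(scenarioSpec(kind = "entrapment", nFrames = 10,
                                       noiseSigma = 0, seed = 41))
  pg <- poreGeometrySeries(g$trajectory)
  expect_equal(pg$width$value, rep(16.7, 10), tolerance = 1e-9)
  expect_equal(pg$minGap$value, rep(2.8, 10), tolerance = 1e-9)
})

test_that("a planted pore-opening step is located at the scheduled frame", {
  g <- generateTrajectory(scenarioSpec(
    kind = "pore_open_close", nFrames = 100, noiseSigma = 0, seed = 42,
    transitionFrames = 1,
    eventSchedule = list(list(time = 500, event = "open"))))
  pg <- poreGeometrySeries(g$trajectory)
  w <- pg$width$value
  jump <- which(diff(w) > 1)
  expect_length(jump, 1L)
  planted <- which.min(abs(trajTimes(g$trajectory) - 500))
  expect_lte(abs(jump - (planted - 1L)), 1L)
  expect_equal(w[100], 16.7 + 3.6, tolerance = 1e-9)
})

test_that("equilibration window detection finds plateaus and honors overrides", {
  tt <- seq(0, 1990, by = 10)
  const <- data.frame(time_ns = tt, value = rep(2, length(tt)))
  expect_equal(equilibrationWindow(list(const, const)),
               c(0, 1990))
  ## ramp to 800 ns then flat
  ramp <- data.frame(time_ns = tt,
                     value = pmin(tt, 800) * 0.01)
  w <- equilibrationWindow(list(ramp))
  winLen <- 0.1 * (max(tt) - min(tt))
  expect_lte(abs(w[1] - 800), winLen + 10)
  expect_equal(w[2], 1990)
  ## explicit override is returned verbatim
  expect_equal(equilibrationWindow(list(ramp), override = c(2000, 3500)),
               c(2000, 3500))
  ## never-flat series fall back to the final 40% with a warning
  noisy <- data.frame(time_ns = tt, value = 0.05 * tt)
  expect_warning(w2 <- equilibrationWindow(list(noisy)), "final 40")
  expect_equal(w2[1], tt[ceiling(0.6 * length(tt))])
})

test_that("nucleotide tracks are zero on the reference and exact on a planted hop", {
  sc <- generateScaffold()
  topo <- sc$topology
  traj1 <- makeTrajectory(topo, sc$reference)
  tr <- nucleotideTrack(traj1, sc$reference, topo@positions[["1"]])
  expect_equal(tr$pDisplacement$value, 0, tolerance = 1e-10)
  expect_equal(tr$heavyRmsd$value, 0, tolerance = 1e-10)

  g <- generateTrajectory(scenarioSpec(kind = "backbone_translocation",
                                       nFrames = 120, noiseSigma = 0,
                                       seed = 43))
  trH <- nucleotideTrack(g$trajectory, g$reference,
                         topology(g$trajectory)@positions[["1"]])
  post <- trH$pDisplacement$time_ns >= 1000
  expect_equal(trH$pDisplacement$value[post],
               rep(7.0, sum(post)), tolerance = 1e-9)
})

test_that("behavior classification recovers every planted scenario class", {
  pc <- poreConfig()
  cases <- list(backbone_translocation = "backbone_translocation",
                base_flip = "base_translocation",
                entrapment = "blocked")
  for (kind in names(cases)) {
    for (seed in c(7, 8)) {
      g <- generateTrajectory(scenarioSpec(kind = kind, seed = seed,
                                           noiseSigma = 0.5))
      topo <- topology(g$trajectory)
      tr <- nucleotideTrack(g$trajectory, g$reference,
                            topo@positions[["1"]], pc)
      lab <- classifyBehavior(tr, c(1000, 1490), topo, g$reference, pc)
      expect_equal(lab$label, cases[[kind]],
                   label = paste(kind, "seed", seed))
      expect_true(is.finite(lab$evidence$meanHeavyRmsd))
    }
  }
})

test_that("classification is invariant under rigid motion and time rescaling", {
  pc <- poreConfig()
  g <- generateTrajectory(scenarioSpec(kind = "base_flip", seed = 44,
                                       noiseSigma = 0.5))
  topo <- topology(g$trajectory)
  tr0 <- nucleotideTrack(g$trajectory, g$reference,
                         topo@positions[["1"]], pc)
  lab0 <- classifyBehavior(tr0, c(1000, 1490), topo, g$reference, pc)
  moved <- g$trajectory
  set.seed(45)
  for (f in seq_len(nFrames(moved))) {
    R <- randomRotation(); t <- rnorm(3, sd = 30)
    moved@coords[, , f] <- sweep(moved@coords[, , f] %*% t(R), 2, t, "+")
  }
  trM <- nucleotideTrack(moved, g$reference, topo@positions[["1"]], pc)
  labM <- classifyBehavior(trM, c(1000, 1490), topo, g$reference, pc)
  expect_equal(labM$label, lab0$label)
  expect_equal(labM$evidence$meanPDisplacement,
               lab0$evidence$meanPDisplacement, tolerance = 1e-6)
  ## order-preserving time rescale
  scaled <- g$trajectory
  scaled@times <- scaled@times * 2
  trS <- nucleotideTrack(scaled, g$reference, topo@positions[["1"]], pc)
  labS <- classifyBehavior(trS, c(2000, 2980), topo, g$reference, pc)
  expect_equal(labS$label, lab0$label)
})

test_that("stage segmentation finds planted contact epochs and ignores flickers", {
  ## constant contacts: one stage, no boundaries
  g0 <- generateTrajectory(scenarioSpec(kind = "entrapment",
                                        nFrames = 40, noiseSigma = 0,
                                        seed = 46))
  pairs <- data.frame(residue = c(196L, 192L), nucleotide = c(41L, 39L))
  seg0 <- segmentStages(g0$trajectory, pairs)
  expect_length(seg0$boundaries, 0L)
  expect_equal(nrow(seg0$fingerprints), 1L)

  ## planted epochs: residue 161 toggles on and off against dT3
  g1 <- generateTrajectory(scenarioSpec(
    kind = "custom", nFrames = 200, noiseSigma = 0, seed = 47,
    transitionFrames = 1,
    eventSchedule = list(
      list(time = 500, event = "contact_on", residue = 161,
           nucleotide = 42),
      list(time = 1200, event = "contact_off", residue = 161,
           nucleotide = 42))))
  pairs1 <- rbind(pairs, data.frame(residue = 161L, nucleotide = 42L))
  seg1 <- segmentStages(g1$trajectory, pairs1)
  filterW <- 0.05 * nFrames(g1$trajectory) * 10  # ns
  expect_length(seg1$boundaries, 2L)
  expect_lte(abs(seg1$boundaries[1] - 500), filterW + 10)
  expect_lte(abs(seg1$boundaries[2] - 1200), filterW + 10)
  ## adjacent fingerprints differ
  expect_false(identical(seg1$fingerprints[1, ], seg1$fingerprints[2, ]))

  ## a 1-frame flicker never creates a boundary (majority + dwell)
  g2 <- generateTrajectory(scenarioSpec(kind = "entrapment",
                                        nFrames = 100, noiseSigma = 0,
                                        seed = 48))
  tr2 <- g2$trajectory
  a <- atomTable(tr2)
  sc161 <- which(a$resno == 161 & a$name != "CA")
  nuc <- which(a$resno == 42 & a$chain == "D")
  delta <- colMeans(tr2@coords[nuc, , 50]) -
    colMeans(tr2@coords[sc161, , 50])
  tr2@coords[sc161, , 50] <- sweep(tr2@coords[sc161, , 50, drop = TRUE],
                                   2, delta * 0.9, "+")
  seg2 <- segmentStages(tr2, pairs1)
  expect_length(seg2$boundaries, 0L)
})

test_that("stage boundary count is monotone non-increasing in the dwell", {
  g <- generateTrajectory(scenarioSpec(
    kind = "custom", nFrames = 200, noiseSigma = 0, seed = 49,
    transitionFrames = 1,
    eventSchedule = list(
      list(time = 400, event = "contact_on", residue = 161,
           nucleotide = 42),
      list(time = 700, event = "contact_off", residue = 161,
           nucleotide = 42),
      list(time = 1400, event = "contact_on", residue = 158,
           nucleotide = 41))))
  pairs <- data.frame(residue = c(161L, 158L), nucleotide = c(42L, 41L))
  dwells <- c(10, 50, 100, 300, 600, 1200)
  counts <- vapply(dwells, function(dw)
    length(segmentStages(g$trajectory, pairs, minDwell = dw)$boundaries),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the representative frame is the brute-force medoid with earliest-tie break", {
  ## identical frames: the first frame wins the tie
  sc <- generateScaffold()
  n <- nrow(sc$reference)
  coords <- array(rep(sc$reference, 5), dim = c(n, 3, 5))
  traj <- makeTrajectory(sc$topology, coords)
  expect_equal(representativeFrame(traj, "calpha", c(0, 4)), 1L)

  ## noise ensemble with one gross outlier: the outlier is never chosen
  set.seed(50)
  coords2 <- coords[, , rep(1, 11)]
  dim(coords2) <- c(n, 3, 11)
  for (f in 1:10) coords2[, , f] <- coords2[, , f] + rnorm(n * 3, 0, 0.3)
  ## incoherent 10 A distortion (a rigid shift would be fitted away)
  coords2[, , 11] <- coords2[, , 11] + matrix(rnorm(n * 3, 0, 10), n, 3)
  traj2 <- makeTrajectory(sc$topology, coords2)
  med <- representativeFrame(traj2, "calpha", c(0, 10))
  expect_lte(med, 10L)

  ## equality with an exhaustive O(n^2) evaluation
  idx <- resolveSelection(sc$topology, "calpha")
  frames <- 1:11
  D <- matrix(0, 11, 11)
  for (i in 1:10) for (j in (i + 1):11) {
    fit <- kabschSuperpose(coords2[, , i], coords2[, , j], idx)
    d <- sqrt(mean(rowSums((fit$coords[idx, ] -
                            coords2[idx, , j])^2)))
    D[i, j] <- d; D[j, i] <- d
  }
  expect_equal(med, frames[which.min(rowSums(D))])
})

test_that("the bend metric separates straight and hairpin strands", {
  ## straight trio at B-form geometry: outer distance above threshold
  b <- buildBFormStrand(3)
  atoms <- data.frame(name = "P", resname = "DT", resno = 1:3,
                      chain = "D", stringsAsFactors = FALSE)
  topo <- makeTopology(atoms)
  traj <- makeTrajectory(topo, array(rep(t(t(b$P)), 2),
                                     dim = c(3, 3, 2)))
  s <- bendSeries(traj, 1:3)
  expect_gt(s$value[1], 9.1)
  expect_false(bendPredicate(s, c(0, 1)))
  ## collinear 7 A spacing: outer distance exactly 14
  m <- cbind(c(0, 7, 14), 0, 0)
  trajC <- makeTrajectory(topo, array(rep(m, 2), dim = c(3, 3, 2)))
  sC <- bendSeries(trajC, 1:3)
  expect_equal(sC$value, c(14, 14))
  ## planted hairpin with outer P-P of 8 A
  h <- rbind(c(0, 0, 0), c(5, 3, 0), c(8, 0, 0))
  trajH <- makeTrajectory(topo, array(rep(h, 2), dim = c(3, 3, 2)))
  sH <- bendSeries(trajH, 1:3)
  expect_equal(sH$value, c(8, 8))
  expect_true(bendPredicate(sH, c(0, 1)))
})

test_that("population tables follow the fixed label order and integer rounding", {
  mk <- function(lbl) list(label = list(label = lbl))
  reps <- c(lapply(1:6, function(i) mk("blocked")),
            lapply(1:2, function(i) mk("base_translocation")),
            list(mk("backbone_translocation")))
  tab <- replicaSummary(reps)
  expect_equal(tab$label, c("backbone_translocation",
                            "base_translocation", "blocked"))
  expect_equal(tab$count, c(1L, 2L, 6L))
  expect_equal(tab$percent, c(11L, 22L, 67L))
  tab1 <- replicaSummary(list(mk("blocked")))
  expect_equal(tab1$percent[tab1$label == "blocked"], 100L)
  expect_equal(sum(tab1$count), 1L)
})
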