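test_that("potential training matches an independent histogram oracle", {
  fx <- testCorpus()[c(1, 3)]
  corpus <- lapply(fx, function(f) f$structure)
  em <- trainPotential(corpus, binWidth = 0.5, maxDist = 15,
                       pseudocount = 0.5)
  # independent oracle: plain-loop histograms over the same pair rules
  nBins <- ceiling(15 / 0.5)
  obs <- matrix(0, 21, nBins)
  pairIdx <- dnassembly:::beadPairIndex
  beads <- c("P", "C4'", "C2'", "C2", "C4", "C6")
  for (f in fx) {
    cm <- coarseGrain(f$structure)
    n <- nResidues(cm)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cm@chain[i] == cm@chain[j] && (j - i) < 2) next
      for (bi in 1:6) for (bj in 1:6) {
        d <- sqrt(sum((cm@coords[(i - 1) * 6 + bi, ] -
                       cm@coords[(j - 1) * 6 + bj, ])^2))
        if (d < 15) {
          b <- min(nBins, floor(d / 0.5) + 1)
          tp <- pairIdx[bi, bj]
          obs[tp, b] <- obs[tp, b] + 1
        }
      }
    }
  }
  binTot <- colSums(obs)
  frac <- rowSums(obs) / sum(obs)
  ref <- outer(frac, binTot)
  expected <- -log((obs + 0.5) / (ref + 0.5))
  expect_equal(unname(em@pairEnergies), unname(expected), tolerance = 1e-10)
})

test_that("a corpus whose observations equal the reference scores zero", {
  # with a single distance bin the quasi-chemical reference equals the
  # observations exactly, so every energy is -ln(1) = 0
  f <- testCorpus()[[1]]
  em <- trainPotential(list(f$structure), binWidth = 25, maxDist = 20)
  expect_true(all(abs(em@pairEnergies) < 1e-12))
  expect_error(trainPotential(list()), "at least one")
  one <- NucleicStructure(f$structure@atoms[f$structure@atoms$rindex == 1, ])
  expect_error(trainPotential(list(one)), "at least one")
})

test_that("movable elements follow the rigidity rules and partition", {
  mk <- function(ss, seq) {
    db <- parseDotBracket(ss)
    buildSST(decomposeSSE(db, seq), db)
  }
  # 4 nt hairpin: rigid; 5 nt hairpin: flexible
  els <- identifyMovableElements(mk("((....))", "GCAAAAGC"))
  hp <- Filter(function(e) e$kind == "hairpin", els)
  expect_length(hp, 1)
  expect_true(hp[[1]]$rigid)
  els <- identifyMovableElements(mk("((.....))", "GCAAAAAGC"))
  hp <- Filter(function(e) e$kind == "hairpin", els)
  expect_length(hp, 5)                   # one element per residue
  expect_false(any(vapply(hp, function(e) e$rigid, TRUE)))
  # 6 nt internal loop rigid, 7 nt flexible
  els <- identifyMovableElements(mk("((...((....))...))",
                                    "GCAAACCAAAAGGAAAGC"))
  il <- Filter(function(e) e$kind == "internal", els)
  expect_length(il, 1)
  expect_true(il[[1]]$rigid)
  els <- identifyMovableElements(mk("((...((....))....))",
                                    "GCAAACCAAAAGGAAAAGC"))
  il <- Filter(function(e) e$kind == "internal", els)
  expect_length(il, 7)
  expect_false(any(vapply(il, function(e) e$rigid, TRUE)))
  # stems always rigid; elements partition all residues
  for (ss in c("((....))", ".(((((.....(((((.&.))))))))))."))
  {
    f <- testCorpus()[[5]]
    tree <- buildSST(decomposeSSE(f$db, f$seq), f$db)
    els <- identifyMovableElements(tree)
    expect_true(all(vapply(Filter(function(e) e$kind == "stem", els),
                           function(e) e$rigid, TRUE)))
    expect_identical(sort(unlist(lapply(els, function(e) e$residues))),
                     seq_len(length(f$db)))
  }
})

test_that("the sampler is deterministic and keeps rigid elements rigid", {
  f <- testCorpus()[[1]]
  tree <- buildSST(decomposeSSE(f$db, f$seq), f$db)
  em <- trainPotential(lapply(testCorpus()[1:6], function(x) x$structure))
  cfg <- samcConfig(nSteps = 1500, nStages = 10, snapshotStride = 250,
                    seed = 5)
  r1 <- samcOptimize(f$structure, tree, em, cfg)
  r2 <- samcOptimize(f$structure, tree, em, cfg)
  expect_equal(r1$snapshots[[length(r1$snapshots)]]$coords,
               r2$snapshots[[length(r2$snapshots)]]$coords)
  expect_equal(r1$finalEnergy, r2$finalEnergy)
  # rigid-element internal bead distances are invariant
  cm0 <- coarseGrain(f$structure)
  last <- r1$snapshots[[length(r1$snapshots)]]$coords
  for (e in seq_along(r1$elements)) {
    el <- r1$elements[[e]]
    if (!el$rigid || length(el$residues) < 2) next
    rows <- rep((el$residues - 1) * 6, each = 6) + 1:6
    d0 <- dist(cm0@coords[rows, ])
    d1 <- dist(last[rows, ])
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  # zero steps returns only the initial snapshot
  r0 <- samcOptimize(f$structure, tree, em, samcConfig(nSteps = 0, seed = 1))
  expect_length(r0$snapshots, 1)
  expect_equal(r0$snapshots[[1]]$coords, cm0@coords)
})

test_that("at very low temperature accepted moves never raise the energy", {
  f <- testCorpus()[[3]]
  tree <- buildSST(decomposeSSE(f$db, f$seq), f$db)
  em <- trainPotential(lapply(testCorpus()[1:6], function(x) x$structure))
  cfg <- samcConfig(nSteps = 1200, tStart = 1e-9, tEnd = 1e-9, nStages = 1,
                    snapshotStride = 25, seed = 9)
  r <- samcOptimize(f$structure, tree, em, cfg)
  en <- vapply(r$snapshots, function(s) s$energy, 1)
  expect_true(all(diff(en) <= 1e-9))
})

test_that("annealing relaxes a purely harmonic chain objective", {
  # convex toy energy: zeroed statistical tables leave only the harmonic
  # connectivity term
  f <- testCorpus()[[1]]
  tree <- buildSST(decomposeSSE(f$db, f$seq), f$db)
  nB <- ceiling(20 / 0.3)
  em <- new("EnergyModel", pairEnergies = matrix(0, 21, nB),
            torsionEnergies = matrix(0, 2, 36,
              dimnames = list(c("eta", "theta"), NULL)),
            binWidth = 0.3, maxDist = 20, pseudocount = 1)
  wins <- 0L
  for (seed in 1:20) {
    cfg <- samcConfig(nSteps = 300, nStages = 12, snapshotStride = 300,
                      seed = seed, kConn = 1)
    r <- samcOptimize(f$structure, tree, em, cfg)
    e0 <- r$snapshots[[1]]$energy
    if (r$finalEnergy <= e0 + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("clustering picks lowest-energy representatives, at most k", {
  f <- testCorpus()[[1]]
  tree <- buildSST(decomposeSSE(f$db, f$seq), f$db)
  em <- trainPotential(lapply(testCorpus()[1:4], function(x) x$structure))
  r <- samcOptimize(f$structure, tree, em,
                    samcConfig(nSteps = 1000, nStages = 5,
                               snapshotStride = 50, seed = 3))
  out <- clusterAndRank(r, f$structure, k = 5)
  expect_lte(length(out), 5)
  en <- vapply(out, function(o) o$energy, 1)
  expect_true(!is.unsorted(en))
  # single snapshot -> single output
  r0 <- samcOptimize(f$structure, tree, em, samcConfig(nSteps = 0, seed = 1))
  expect_length(clusterAndRank(r0, f$structure), 1)
  # many copies of one conformation collapse to one cluster
  rDup <- r0
  rDup$snapshots <- rep(r0$snapshots, 50)
  expect_length(clusterAndRank(rDup, f$structure), 1)
  # well-separated snapshots with energies {3,1,2}, k = 2 -> energies 1, 2
  mkSnap <- function(shift, energy) {
    co <- coarseGrain(f$structure)@coords
    co[1:6, ] <- co[1:6, ] + shift          # deform, not a rigid motion
    list(coords = co, energy = energy,
         transforms = r0$snapshots[[1]]$transforms)
  }
  rMix <- r0
  rMix$snapshots <- list(mkSnap(c(0, 0, 0), 3), mkSnap(c(30, 0, 0), 1),
                         mkSnap(c(0, 40, 0), 2))
  out2 <- clusterAndRank(rMix, f$structure, k = 2)
  expect_equal(vapply(out2, function(o) o$energy, 1), c(1, 2))
})

test_that("fixed-temperature occupancies obey the Boltzmann ratio", {
  # a two-residue toy with a single pseudo-torsion and a step potential on
  # its sign: both half-spaces have equal phase-space measure, so the
  # occupancy ratio must follow exp(-dE/T)
  fx <- generateFixtures(fixtureSpec(list(list(id = "TOY", ss = "..",
                                               seq = "AT"))))
  toy <- fx[[1]]$structure
  tree <- buildSST(decomposeSSE(fx[[1]]$db, "AT"), fx[[1]]$db)
  nB <- ceiling(20 / 0.3)
  te <- matrix(0, 2, 36, dimnames = list(c("eta", "theta"), NULL))
  dE <- 1
  te["theta", 19:36] <- dE
  em <- new("EnergyModel", pairEnergies = matrix(0, 21, nB),
            torsionEnergies = te, binWidth = 0.3, maxDist = 20,
            pseudocount = 1)
  cfg <- samcConfig(nSteps = 30000, tStart = 1, tEnd = 1, nStages = 1,
                    snapshotStride = 10, seed = 11, kConn = 0.5)
  r <- samcOptimize(toy, tree, em, cfg)
  th <- vapply(r$snapshots, function(sn) {
    X <- sn$coords
    dnassembly:::dihedralAngle(X[1, , drop = FALSE], X[2, , drop = FALSE],
                               X[7, , drop = FALSE], X[8, , drop = FALSE])
  }, 1)
  th <- th[-(1:300)]                       # burn-in
  up <- th > 0
  phat <- mean(up)
  nb <- 20
  bs <- floor(length(up) / nb)
  bm <- vapply(1:nb, function(b) mean(up[((b - 1) * bs + 1):(b * bs)]), 1)
  se <- stats::sd(bm) / sqrt(nb)
  expected <- exp(-dE) / (1 + exp(-dE))
  expect_lt(abs(phat - expected), 3 * se + 1e-12)
})
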