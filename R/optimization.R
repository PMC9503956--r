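## Coarse-grained refinement: a trainable distance + pseudo-torsion
## statistical potential, residue-level simulated-annealing Monte Carlo
## with rigid helices and short loops, and RMSD-threshold clustering of the
## sampled conformations.

N_BEADS <- 6L
# unordered bead-type pair index (21 combinations of the 6 bead names)
beadPairIndex <- local({
  m <- matrix(0L, N_BEADS, N_BEADS)
  k <- 0L
  for (i in 1:N_BEADS) for (j in i:N_BEADS) {
    k <- k + 1L
    m[i, j] <- k; m[j, i] <- k
  }
  m
})
N_PAIRTYPES <- 21L

# four-point dihedral for matrices of row-aligned points, in degrees
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cbind(n1[, 2] * b2n[, 3] - n1[, 3] * b2n[, 2],
              n1[, 3] * b2n[, 1] - n1[, 1] * b2n[, 3],
              n1[, 1] * b2n[, 2] - n1[, 2] * b2n[, 1])
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# interacting bead pairs of a coarse model: residues i < j on different
# chains or separated by >= 2 along the chain; all 36 bead combinations
pairListOf <- function(cm) {
  n <- nResidues(cm)
  if (n < 2L) return(list(ii = integer(0), jj = integer(0),
                          type = integer(0)))
  rp <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- cm@chain[rp[, 1]] != cm@chain[rp[, 2]] |
    (rp[, 2] - rp[, 1]) >= 2L
  rp <- rp[keep, , drop = FALSE]
  bi <- rep(1:N_BEADS, times = N_BEADS)
  bj <- rep(1:N_BEADS, each = N_BEADS)
  ii <- rep((rp[, 1] - 1L) * N_BEADS, each = 36L) + bi
  jj <- rep((rp[, 2] - 1L) * N_BEADS, each = 36L) + bj
  type <- rep(beadPairIndex[cbind(bi, bj)], times = nrow(rp))
  list(ii = ii, jj = jj, type = type)
}

# pseudo-torsion atom quadruples (rows into the bead coordinate matrix);
# eta: C4'(i-1), P(i), C4'(i), P(i+1); theta: P(i), C4'(i), P(i+1), C4'(i+1)
torsionListOf <- function(cm) {
  n <- nResidues(cm)
  Prow <- function(k) (k - 1L) * N_BEADS + 1L
  C4row <- function(k) (k - 1L) * N_BEADS + 2L
  eta <- NULL; theta <- NULL
  for (ch in unique(cm@chain)) {
    res <- which(cm@chain == ch)
    m <- length(res)
    if (m >= 3L) {
      i <- res[2:(m - 1L)]
      eta <- rbind(eta, cbind(C4row(i - 1L), Prow(i), C4row(i),
                              Prow(i + 1L)))
    }
    if (m >= 2L) {
      i <- res[1:(m - 1L)]
      theta <- rbind(theta, cbind(Prow(i), C4row(i), Prow(i + 1L),
                                  C4row(i + 1L)))
    }
  }
  list(eta = eta, theta = theta)
}

#' Train the statistical potential from a corpus
#'
#' Accumulates distance histograms over all interacting bead pairs (bin
#' width \code{binWidth}, range 0 to \code{maxDist}) and pseudo-torsion
#' histograms (10 degree bins) over the coarse-grained corpus, then
#' converts them to energies \eqn{E = -\ln((obs + c)/(ref + c))} with a
#' quasi-chemical reference: the bin total over all bead-type pairs,
#' apportioned by each type's overall frequency.
#'
#' @param corpus list of [NucleicStructure-class] / [CoarseModel-class]
#'   objects, or a [TemplateLibrary-class] (its fragments are used)
#' @param binWidth distance bin width in Angstrom (default 0.3)
#' @param maxDist upper end of the distance range (default 20)
#' @param pseudocount pseudocount \code{c} (default 1)
#' @return an [EnergyModel-class]
#' @export
trainPotential <- function(corpus, binWidth = 0.3, maxDist = 20,
                           pseudocount = 1) {
  if (is(corpus, "TemplateLibrary"))
    corpus <- lapply(corpus@templates, function(t) t@fragment)
  cms <- lapply(corpus, function(s)
    if (is(s, "CoarseModel")) s else coarseGrain(s))
  cms <- Filter(function(cm) nResidues(cm) >= 2L, cms)
  if (!length(cms))
    stop("corpus must contain at least one structure with >= 2 residues")
  nBins <- as.integer(ceiling(maxDist / binWidth))
  obsD <- matrix(0, N_PAIRTYPES, nBins)
  nTorsBins <- 36L
  obsT <- matrix(0, 2, nTorsBins, dimnames = list(c("eta", "theta"), NULL))
  for (cm in cms) {
    pl <- pairListOf(cm)
    if (length(pl$ii)) {
      d <- sqrt(rowSums((cm@coords[pl$ii, , drop = FALSE] -
                         cm@coords[pl$jj, , drop = FALSE])^2))
      keep <- d < maxDist
      if (any(keep)) {
        bin <- pmin(nBins, floor(d[keep] / binWidth) + 1L)
        tb <- table(factor(pl$type[keep], levels = 1:N_PAIRTYPES),
                    factor(bin, levels = 1:nBins))
        obsD <- obsD + unclass(tb)
      }
    }
    tl <- torsionListOf(cm)
    for (tt in c("eta", "theta")) {
      q <- tl[[tt]]
      if (is.null(q)) next
      ang <- dihedralAngle(cm@coords[q[, 1], , drop = FALSE],
                           cm@coords[q[, 2], , drop = FALSE],
                           cm@coords[q[, 3], , drop = FALSE],
                           cm@coords[q[, 4], , drop = FALSE])
      bin <- pmin(nTorsBins, floor((ang + 180) / 10) + 1L)
      obsT[tt, ] <- obsT[tt, ] +
        tabulate(bin, nbins = nTorsBins)
    }
  }
  quasiChemical <- function(obs) {
    binTot <- colSums(obs)
    typeFrac <- rowSums(obs) / max(1, sum(obs))
    ref <- outer(typeFrac, binTot)
    -log((obs + pseudocount) / (ref + pseudocount))
  }
  new("EnergyModel", pairEnergies = quasiChemical(obsD),
      torsionEnergies = quasiChemical(obsT),
      binWidth = binWidth, maxDist = maxDist, pseudocount = pseudocount)
}

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf(
    "EnergyModel: %d bead-pair types x %d distance bins (%.2f A), %d torsion bins\n",
    nrow(object@pairEnergies), ncol(object@pairEnergies), object@binWidth,
    ncol(object@torsionEnergies)))
})

# total potential energy of bead coordinates X under the model, plus a
# harmonic chain-connectivity term on consecutive P-P distances
coarseEnergy <- function(X, em, pl, tl, connIdx, kConn = 0.2, connR0 = 6.5) {
  e <- 0
  if (length(pl$ii)) {
    d <- sqrt(rowSums((X[pl$ii, , drop = FALSE] -
                       X[pl$jj, , drop = FALSE])^2))
    nBins <- ncol(em@pairEnergies)
    keep <- d < em@maxDist
    if (any(keep)) {
      bin <- pmin(nBins, floor(d[keep] / em@binWidth) + 1L)
      e <- e + sum(em@pairEnergies[cbind(pl$type[keep], bin)])
    }
  }
  for (tt in c("eta", "theta")) {
    q <- tl[[tt]]
    if (is.null(q)) next
    ang <- dihedralAngle(X[q[, 1], , drop = FALSE], X[q[, 2], , drop = FALSE],
                         X[q[, 3], , drop = FALSE], X[q[, 4], , drop = FALSE])
    bin <- pmin(36L, floor((ang + 180) / 10) + 1L)
    e <- e + sum(em@torsionEnergies[tt, bin])
  }
  if (nrow(connIdx)) {
    d <- sqrt(rowSums((X[connIdx[, 1], , drop = FALSE] -
                       X[connIdx[, 2], , drop = FALSE])^2))
    e <- e + kConn * sum((d - connR0)^2)
  }
  e
}

#' Identify the movable elements for coarse-grained refinement
#'
#' The conformation of every helix is fixed (only its orientation moves);
#' short loops are likewise rigid: hairpin loops with fewer than 5
#' unpaired nucleotides and internal or bulge loops with fewer than 7.
#' All other loops are flexible and move residue by residue.
#'
#' @param tree a [SecondaryStructureTree-class]
#' @return list of elements, each a list with \code{residues} (global
#'   positions), \code{rigid} (flag) and \code{kind}
#' @export
identifyMovableElements <- function(tree) {
  out <- list()
  for (sse in tree@sses) {
    paired <- if (nrow(sse@pairs)) c(sse@pairs[, 1], sse@pairs[, 2])
              else integer(0)
    if (sse@kind == "stem") {
      out[[length(out) + 1L]] <- list(residues = sse@positions,
                                      rigid = TRUE, kind = "stem")
      next
    }
    loopRes <- setdiff(sse@positions, paired)
    if (!length(loopRes)) next
    rigid <- (sse@kind == "hairpin" && length(loopRes) < 5L) ||
             (sse@kind %in% c("internal", "bulge") && length(loopRes) < 7L)
    if (rigid) {
      out[[length(out) + 1L]] <- list(residues = loopRes, rigid = TRUE,
                                      kind = sse@kind)
    } else {
      for (r in loopRes)
        out[[length(out) + 1L]] <- list(residues = r, rigid = FALSE,
                                        kind = sse@kind)
    }
  }
  out
}

#' Configuration for the simulated-annealing Monte Carlo sampler
#'
#' @param nSteps total number of proposals (default 100000)
#' @param tStart,tEnd start / end temperature in energy units of the
#'   trained potential (defaults 5 and 0.1)
#' @param nStages number of geometric cooling stages (default 50)
#' @param maxTranslation maximum translation per move, Angstrom (default 2)
#' @param maxRotation maximum rotation per move, degrees (default 15)
#' @param snapshotStride record a snapshot every this many proposals
#'   (default 500)
#' @param seed RNG seed (NULL leaves the RNG state alone)
#' @param kConn,connR0 harmonic chain-connectivity term: force constant
#'   and target consecutive P-P distance in Angstrom
#' @return a validated configuration list
#' @export
samcConfig <- function(nSteps = 100000, tStart = 5, tEnd = 0.1,
                       nStages = 50, maxTranslation = 2, maxRotation = 15,
                       snapshotStride = 500, seed = NULL, kConn = 0.2,
                       connR0 = 6.5) {
  stopifnot(tStart >= tEnd, tEnd > 0, nSteps >= 0, nStages >= 1)
  list(nSteps = as.integer(nSteps), tStart = tStart, tEnd = tEnd,
       nStages = as.integer(nStages), maxTranslation = maxTranslation,
       maxRotation = maxRotation, snapshotStride = as.integer(snapshotStride),
       seed = seed, kConn = kConn, connR0 = connR0)
}

rotationAboutAxis <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Coarse-grained simulated-annealing Monte Carlo refinement
#'
#' At each step one movable element is chosen at random and translated,
#' rotated around a point (its centroid) or rotated around an axis through
#' its first phosphate; the move is accepted by the Metropolis criterion
#' at the current temperature, which decays geometrically from
#' \code{tStart} to \code{tEnd}.  A harmonic term on consecutive P-P
#' distances keeps the chain from fragmenting.  Trajectories are exactly
#' reproducible for a given seed.
#'
#' @param assembled the assembled all-atom [NucleicStructure-class]
#' @param tree the target's [SecondaryStructureTree-class]
#' @param em a trained [EnergyModel-class]
#' @param cfg a configuration from [samcConfig()]
#' @return list with \code{snapshots} (each: \code{coords}, \code{energy},
#'   \code{transforms}), \code{elements}, \code{finalEnergy} and
#'   \code{acceptanceRate}
#' @export
samcOptimize <- function(assembled, tree, em, cfg = samcConfig()) {
  cm <- coarseGrain(assembled)
  n <- nResidues(cm)
  elements <- identifyMovableElements(tree)
  if (!length(elements)) stop("no movable elements")
  covered <- sort(unlist(lapply(elements, function(e) e$residues)))
  if (!identical(covered, seq_len(n)))
    stop("movable elements do not partition the residues")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  elemRows <- lapply(elements, function(e)
    rep((e$residues - 1L) * N_BEADS, each = N_BEADS) + 1:N_BEADS)
  pl <- pairListOf(cm)
  tl <- torsionListOf(cm)
  Prow <- function(k) (k - 1L) * N_BEADS + 1L
  connIdx <- NULL
  for (ch in unique(cm@chain)) {
    res <- which(cm@chain == ch)
    if (length(res) >= 2L)
      connIdx <- rbind(connIdx, cbind(Prow(res[-length(res)]),
                                      Prow(res[-1L])))
  }
  if (is.null(connIdx)) connIdx <- matrix(0L, 0, 2)
  X <- cm@coords
  E <- coarseEnergy(X, em, pl, tl, connIdx, cfg$kConn, cfg$connR0)
  transforms <- lapply(elements, function(e) list(R = diag(3), t = c(0, 0, 0)))
  snapshots <- list(list(coords = X, energy = E, transforms = transforms))
  if (cfg$nSteps == 0L)
    return(list(snapshots = snapshots, elements = elements,
                finalEnergy = E, acceptanceRate = NA_real_))
  stage <- rep(seq_len(cfg$nStages), length.out = cfg$nSteps)
  stage <- sort(stage)
  fCool <- if (cfg$nStages == 1L) 1 else
    (cfg$tEnd / cfg$tStart)^(1 / (cfg$nStages - 1))
  temps <- cfg$tStart * fCool^(stage - 1L)
  nAcc <- 0L
  for (step in seq_len(cfg$nSteps)) {
    e <- sample.int(length(elements), 1L)
    rows <- elemRows[[e]]
    mt <- sample.int(3L, 1L)
    if (mt == 1L) {
      Rm <- diag(3)
      tm <- randomUnitVector() * stats::runif(1, 0, cfg$maxTranslation)
    } else {
      center <- if (mt == 2L) colMeans(X[rows, , drop = FALSE])
                else X[Prow(elements[[e]]$residues[1L]), ]
      Rm <- rotationAboutAxis(randomUnitVector(),
                              stats::runif(1, -cfg$maxRotation,
                                           cfg$maxRotation))
      tm <- center - as.numeric(Rm %*% center)
    }
    Xn <- X
    Xn[rows, ] <- X[rows, , drop = FALSE] %*% t(Rm) +
      matrix(tm, length(rows), 3, byrow = TRUE)
    En <- coarseEnergy(Xn, em, pl, tl, connIdx, cfg$kConn, cfg$connR0)
    dE <- En - E
    if (dE <= 0 || stats::runif(1) < exp(-dE / temps[step])) {
      X <- Xn; E <- En; nAcc <- nAcc + 1L
      old <- transforms[[e]]
      transforms[[e]] <- list(R = Rm %*% old$R,
                              t = as.numeric(Rm %*% old$t) + tm)
    }
    if (step %% cfg$snapshotStride == 0L || step == cfg$nSteps)
      snapshots[[length(snapshots) + 1L]] <-
        list(coords = X, energy = E, transforms = transforms)
  }
  list(snapshots = snapshots, elements = elements, finalEnergy = E,
       acceptanceRate = nAcc / cfg$nSteps)
}

# rebuild the all-atom structure of a snapshot by applying each element's
# cumulative rigid transform to the assembled structure
reconstructAllAtom <- function(assembled, elements, transforms) {
  a <- assembled@atoms
  for (e in seq_along(elements)) {
    tr <- transforms[[e]]
    rows <- which(a$rindex %in% elements[[e]]$residues)
    m <- applyTransform(as.matrix(a[rows, c("x", "y", "z")]), tr)
    a$x[rows] <- m[, 1]; a$y[rows] <- m[, 2]; a$z[rows] <- m[, 3]
  }
  initialize(assembled, atoms = a)
}

#' Cluster sampled conformations and return the top-ranked structures
#'
#' Greedy RMSD-threshold clustering on the coarse beads
#' (descending-population assignment); each cluster is represented by its
#' lowest-energy member, and up to \code{k} representatives are returned
#' sorted by energy, reconstructed at all-atom detail by applying the
#' elements' rigid transform history to the assembled structure.
#'
#' @param samc result of [samcOptimize()]
#' @param assembled the all-atom assembly the sampler started from
#' @param k maximum number of output structures (default 5)
#' @param threshold RMSD clustering threshold in Angstrom (default 2)
#' @return list of lists with \code{structure} ([NucleicStructure-class])
#'   and \code{energy}, energy-ascending; at most \code{k} entries
#' @export
clusterAndRank <- function(samc, assembled, k = 5, threshold = 2) {
  snaps <- samc$snapshots
  m <- length(snaps)
  stopifnot(m >= 1L)
  energies <- vapply(snaps, function(s) s$energy, 1)
  if (m == 1L) {
    reps <- 1L
  } else {
    D <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      D[i, j] <- D[j, i] <-
        kabsch(snaps[[i]]$coords, snaps[[j]]$coords)$rmsd
    }
    remaining <- seq_len(m)
    reps <- integer(0)
    while (length(remaining)) {
      counts <- vapply(remaining, function(i)
        sum(D[i, remaining] <= threshold), 1L)
      pick <- remaining[which.max(counts)]
      members <- remaining[D[pick, remaining] <= threshold]
      reps <- c(reps, members[which.min(energies[members])])
      remaining <- setdiff(remaining, members)
    }
  }
  reps <- reps[order(energies[reps])]
  reps <- reps[seq_len(min(k, length(reps)))]
  lapply(reps, function(i)
    list(structure = reconstructAllAtom(assembled, samc$elements,
                                        snaps[[i]]$transforms),
         energy = energies[i]))
}
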