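## Ideal-geometry construction: B-form helices from the internal repeating
## unit, and smooth-arc placement of unpaired loop nucleotides.  Used by the
## de novo template fallback and by the synthetic fixture generator.

rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# transform of helical step k (0-based): rotate k*twist, rise k*rise along z
stepTransform <- function(k, twist = 36, rise = 3.38) {
  list(R = rotZ(k * twist), t = c(0, 0, k * rise))
}

# two-fold flip about x: maps a strand-1 unit onto its paired partner
FLIP_D <- diag(c(1, -1, -1))

applyRT <- function(m, R, t) {
  m %*% t(R) + matrix(t, nrow(m), 3, byrow = TRUE)
}

letterToDeoxy <- function(letter) {
  m <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DT")
  out <- m[toupper(letter)]
  if (anyNA(out)) stop("unknown nucleotide letter")
  unname(out)
}

# ideal residue coordinates placed at helical stack index k; flip = strand
# 2.  The repeating unit's backbone closes 5'->3' along -z, so stack index
# k maps to helical step -k: ascending k follows strand 1 in sequence
# order while keeping the helix right-handed.
placedUnit <- function(letter, k, flip = FALSE, twist = 36, rise = 3.38) {
  m <- idealResidue(letterToDeoxy(letter))
  if (flip) m <- m %*% t(FLIP_D)
  st <- stepTransform(-k, twist, rise)
  applyRT(m, st$R, st$t)
}

# local (frame-free) conformation of an ideal residue for chain walking:
# origin at P, x along P->O3', y in the P->C1' half-plane
localUnit <- function(letter) {
  m <- idealResidue(letterToDeoxy(letter))
  o <- m["P", ]
  ex <- m["O3'", ] - o
  ex <- ex / sqrt(sum(ex^2))
  v <- m["C1'", ] - o
  ez <- crossProd(ex, v)
  ez <- ez / sqrt(sum(ez^2))
  ey <- crossProd(ez, ex)
  sweep(m, 2, o) %*% t(rbind(ex, ey, ez))
}

# orthonormal frame with x = tangent and z close to `up`
walkFrame <- function(tangent, up) {
  ex <- tangent / sqrt(sum(tangent^2))
  ez <- up - sum(up * ex) * ex
  nz <- sqrt(sum(ez^2))
  if (nz < 1e-8) {
    ez <- c(-ex[2], ex[1], 0)
    nz <- sqrt(sum(ez^2))
    if (nz < 1e-8) { ez <- c(1, 0, 0); nz <- 1 }
  }
  ez <- ez / nz
  ey <- crossProd(ez, ex)
  rbind(ex, ey, ez)
}

# circular arc through A and B with apex displaced by `bulge` along `dir`
# (dir unit, perpendicular to B-A); bulge 0 degenerates to the chord, and
# bulge > half the chord gives a reflex (> semicircle) arc
arcFun <- function(A, B, dir, bulge) {
  chord <- B - A
  L <- sqrt(sum(chord^2))
  if (bulge < 1e-6) {
    force(L)
    return(list(len = L, point = function(s) A + (s / L) * chord,
                tangent = function(s) chord / L))
  }
  half <- L / 2
  Rr <- (half^2 + bulge^2) / (2 * bulge)      # circle radius
  Mid <- (A + B) / 2
  Cc <- Mid + (bulge - Rr) * dir              # circle center
  u <- (A - Cc) / sqrt(sum((A - Cc)^2))
  # in-plane direction so that the sweep passes through the apex
  v2 <- dir - sum(dir * u) * u
  v2 <- v2 / sqrt(sum(v2^2))
  ang <- 2 * atan2(half, Rr - bulge)          # total sweep, reflex-capable
  arcLen <- Rr * ang
  point <- function(s) {
    th <- (s / arcLen) * ang
    Cc + Rr * (cos(th) * u + sin(th) * v2)
  }
  tangent <- function(s) {
    th <- (s / arcLen) * ang
    tg <- -sin(th) * u + cos(th) * v2
    tg / sqrt(sum(tg^2))
  }
  list(len = arcLen, point = point, tangent = tangent)
}

# place loop residues along a path; returns list of coordinate matrices.
# anchors are list(point=, tangent=); either may be NULL.
#  - both: walk a circular arc from start to end, bulge height chosen to
#    minimize the final O3'-P closure gap
#  - start only / end only: straight walk forward / backward
walkLoopSegment <- function(letters, startAnchor, endAnchor, hint = c(1, 0, 0)) {
  n <- length(letters)
  if (!n) return(list())
  locals <- lapply(letters, localUnit)
  spans <- vapply(locals, function(L) sqrt(sum(L[rownames(L) == "O3'", ]^2)),
                  1)
  walkForward <- function(path, s0, up0) {
    # exact chaining: each residue's P sits 1.6 A past the previous O3';
    # the arc only supplies the local tangent (and hence curvature)
    out <- vector("list", n)
    s <- s0
    up <- up0
    p <- path$point(min(s, path$len))
    for (k in seq_len(n)) {
      tg <- path$tangent(min(s, path$len))
      W <- walkFrame(tg, up)
      out[[k]] <- applyRT(locals[[k]], t(W), p)   # local %*% W + p
      up <- W[3, ]
      s <- s + spans[k] + 1.6
      o3 <- out[[k]][rownames(locals[[k]]) == "O3'", ]
      p <- o3 + 1.6 * path$tangent(min(s, path$len))
    }
    out
  }
  if (!is.null(startAnchor) && !is.null(endAnchor)) {
    A <- startAnchor$point + 1.6 * startAnchor$tangent
    B <- endAnchor$point
    chord <- B - A
    Lc <- sqrt(sum(chord^2))
    if (Lc < 1e-6) { B <- A + c(1e-3, 0, 0); chord <- B - A; Lc <- 1e-3 }
    dir <- hint - sum(hint * chord / Lc) * chord / Lc
    if (sqrt(sum(dir^2)) < 1e-8) dir <- walkFrame(chord / Lc, c(0, 0, 1))[3, ]
    dir <- dir / sqrt(sum(dir^2))
    need <- sum(spans) + 1.6 * n                   # path length to consume
    best <- NULL
    for (sgn in c(1, -1)) {
      for (b in seq(0, max(need, 2 * Lc), length.out = 41)) {
        path <- arcFun(A, B, sgn * dir, b)
        placed <- walkForward(path, 0, sgn * dir)
        o3 <- placed[[n]][rownames(locals[[n]]) == "O3'", ]
        gap <- abs(sqrt(sum((B - o3)^2)) - 1.6)
        if (is.null(best) || gap < best$gap)
          best <- list(gap = gap, placed = placed)
      }
      if (best$gap < 0.25) break
    }
    best$placed
  } else if (!is.null(startAnchor)) {
    A <- startAnchor$point + 1.6 * startAnchor$tangent
    far <- A + (sum(spans) + 1.6 * n + 10) * startAnchor$tangent
    path <- arcFun(A, far, c(0, 0, 1), 0)
    walkForward(path, 0, if (abs(startAnchor$tangent[3]) > 0.9)
      c(1, 0, 0) else c(0, 0, 1))
  } else if (!is.null(endAnchor)) {
    tg <- endAnchor$tangent
    up <- if (abs(tg[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    out <- vector("list", n)
    target <- endAnchor$point - 1.6 * tg           # O3' of last residue
    for (k in rev(seq_len(n))) {
      W <- walkFrame(tg, up)
      o3local <- locals[[k]][rownames(locals[[k]]) == "O3'", ]
      Ppos <- target - as.numeric(o3local %*% W)
      out[[k]] <- applyRT(locals[[k]], t(W), Ppos)
      target <- Ppos - 1.6 * tg
    }
    out
  } else {
    path <- arcFun(c(0, 0, 0), c(sum(spans) + 1.6 * n + 10, 0, 0),
                   c(0, 0, 1), 0)
    walkForward(path, 0, c(0, 0, 1))
  }
}

# group the boundary pairs of a loop SSE into helix stubs (rows adjacent on
# both strands); returns list of row-index vectors into sse@pairs
stubGroups <- function(pairsMat) {
  if (!nrow(pairsMat)) return(list())
  ord <- order(pairsMat[, 1L])
  groups <- list(ord[1L])
  if (nrow(pairsMat) > 1L) {
    for (r in ord[-1L]) {
      gprev <- groups[[length(groups)]]
      last <- gprev[length(gprev)]
      if (pairsMat[r, 1L] == pairsMat[last, 1L] + 1L &&
          pairsMat[r, 2L] == pairsMat[last, 2L] - 1L) {
        groups[[length(groups)]] <- c(gprev, r)
      } else groups[[length(groups) + 1L]] <- r
    }
  }
  groups
}

# assemble per-position coordinate matrices into a NucleicStructure;
# chains follow the global chain assignment of `db` restricted to members
fragmentFromCoords <- function(positions, coordsByPos, letters, db) {
  ci <- chainIndex(db)[positions]
  chains <- LETTERS[match(ci, unique(ci))]
  rows <- list()
  resno <- 0L
  lastChain <- ""
  for (k in seq_along(positions)) {
    if (chains[k] != lastChain) { resno <- 0L; lastChain <- chains[k] }
    resno <- resno + 1L
    m <- coordsByPos[[k]]
    rows[[k]] <- data.frame(chain = chains[k], resno = resno, inscode = "",
                            resname = letterToDeoxy(letters[k]),
                            elety = rownames(m), x = m[, 1], y = m[, 2],
                            z = m[, 3], stringsAsFactors = FALSE)
  }
  NucleicStructure(do.call(rbind, rows))
}

# build all member residues of one SSE from ideal geometry; returns a
# NucleicStructure whose residues follow the sorted member positions
buildIdealFragment <- function(sse, letters, db, twist = 36, rise = 3.38) {
  positions <- sse@positions
  stopifnot(length(letters) == length(positions))
  coordsByPos <- vector("list", length(positions))
  names(coordsByPos) <- as.character(positions)
  setPos <- function(pos, m) coordsByPos[[as.character(pos)]] <<- m
  letterAt <- function(pos) letters[match(pos, positions)]
  pm <- sse@pairs
  if (sse@kind == "stem") {
    for (k in seq_len(nrow(pm))) {
      setPos(pm[k, 1], placedUnit(letterAt(pm[k, 1]), k - 1, FALSE, twist, rise))
      setPos(pm[k, 2], placedUnit(letterAt(pm[k, 2]), k - 1, TRUE, twist, rise))
    }
  } else {
    groups <- stubGroups(pm)
    # the closing stub (if any) encloses all other members
    closing <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      lo <- min(pm[g, 1]); hi <- max(pm[g, 2])
      others <- setdiff(positions, c(pm[g, 1], pm[g, 2]))
      if (length(others) && all(others > lo & others < hi)) closing <- gi
    }
    step <- 0L
    placeStub <- function(g, fromStep, extra = NULL) {
      for (kk in seq_along(g)) {
        r <- g[kk]
        m1 <- placedUnit(letterAt(pm[r, 1]), fromStep + kk - 1, FALSE,
                         twist, rise)
        m2 <- placedUnit(letterAt(pm[r, 2]), fromStep + kk - 1, TRUE,
                         twist, rise)
        if (!is.null(extra)) {
          m1 <- applyRT(m1, extra$R, extra$t)
          m2 <- applyRT(m2, extra$R, extra$t)
        }
        setPos(pm[r, 1], m1); setPos(pm[r, 2], m2)
      }
    }
    arm <- 0L
    if (closing > 0L) {
      g <- groups[[closing]]
      placeStub(g, 0L)
      step <- length(g)
    }
    childGroups <- if (closing > 0L) groups[-closing] else groups
    for (gi in seq_along(childGroups)) {
      g <- childGroups[[gi]]
      if (closing == 0L) {
        # exterior stubs: body of helix grows +z, dangles extend below;
        # successive stubs offset sideways
        extra <- if (gi == 1L) NULL else
          list(R = diag(3), t = c(18 * (gi - 1L), 0, 0))
        placeStub(g, 0L, extra)
      } else if (gi == 1L) {
        placeStub(g, step)                       # coaxial continuation
      } else {
        # additional junction arms: tilt away and swing around the axis
        # (stack indices map to -z, hence the sign of the pivot offset)
        ang <- 55
        Rtilt <- matrix(c(1, 0, 0, 0, cos(ang * pi / 180), sin(ang * pi / 180),
                          0, -sin(ang * pi / 180), cos(ang * pi / 180)), 3, 3)
        Rsw <- rotZ(120 * (gi - 1L))
        zoff <- c(0, 0, -(step - 1) * rise)
        tv <- as.numeric(Rsw %*% Rtilt %*% (-zoff)) + zoff + c(0, 0, -rise)
        placeStub(g, step, list(R = Rsw %*% Rtilt, t = tv))
      }
    }
  }
  # unpaired members: walk arcs/dangles between anchored neighbours
  paired <- if (nrow(pm)) c(pm[, 1], pm[, 2]) else integer(0)
  unpairedRuns <- split(setdiff(positions, paired),
                        cumsum(c(1, diff(setdiff(positions, paired)) != 1)))
  brk <- db@breakAfter
  centroidAll <- function() {
    # backbone atoms only, so the arc-side choice (and hence the loop
    # geometry) depends on the topology alone, not on the sequence
    done <- Filter(Negate(is.null), coordsByPos)
    if (!length(done)) return(c(0, 0, 0))
    m <- do.call(rbind, lapply(done, function(x)
      x[rownames(x) %in% BACKBONE_SUGAR, , drop = FALSE]))
    colMeans(m)
  }
  for (run in unpairedRuns) {
    if (!length(run)) next
    prevPos <- run[1] - 1L
    nextPos <- run[length(run)] + 1L
    startAnchor <- NULL
    endAnchor <- NULL
    if (prevPos %in% positions && !is.null(coordsByPos[[as.character(prevPos)]]) &&
        !(prevPos %in% brk)) {
      m <- coordsByPos[[as.character(prevPos)]]
      o3 <- m[rownames(m) == "O3'", ]
      pp <- m[rownames(m) == "P", ]
      tg <- o3 - pp
      startAnchor <- list(point = o3, tangent = tg / sqrt(sum(tg^2)))
    }
    if (nextPos %in% positions && !is.null(coordsByPos[[as.character(nextPos)]]) &&
        !((nextPos - 1L) %in% brk)) {
      m <- coordsByPos[[as.character(nextPos)]]
      o3 <- m[rownames(m) == "O3'", ]
      pp <- m[rownames(m) == "P", ]
      tg <- o3 - pp
      endAnchor <- list(point = pp, tangent = tg / sqrt(sum(tg^2)))
    }
    hint <- c(1, 0, 0)
    if (!is.null(startAnchor) && !is.null(endAnchor)) {
      mid <- (startAnchor$point + endAnchor$point) / 2
      hint <- mid - centroidAll()
      if (sqrt(sum(hint^2)) < 1e-6) hint <- c(1, 0, 0)
    }
    placed <- walkLoopSegment(vapply(run, letterAt, ""), startAnchor,
                              endAnchor, hint)
    for (k in seq_along(run)) setPos(run[k], placed[[k]])
  }
  fragmentFromCoords(positions, coordsByPos, letters, db)
}
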