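## Rigid superposition and template assembly: adjoining SSE templates are
## merged by superposing the up-to-two base pairs they share (Kabsch), then
## the sequence is mutated to the target and chain connectivity is repaired
## by a restrained harmonic minimizer.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{P} transformed onto \code{Q}.  Reflections are corrected by a sign
#' flip of the smallest singular direction, so the returned rotation always
#' has determinant +1.  Collinear point sets still return a minimizing
#' transform (the rotation about the line is fixed deterministically by the
#' SVD).
#'
#' @param P n x 3 matrix of source points (n >= 3)
#' @param Q n x 3 matrix of target points
#' @return list with elements \code{R} (3 x 3 rotation), \code{t}
#'   (length-3 translation) and \code{rmsd}; the transform maps x to
#'   \code{R x + t}
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' kabsch(P, P)$rmsd   # 0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets must have equal size")
  if (nrow(P) < 3L) stop("at least 3 points are required")
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  moved <- applyTransform(P, list(R = R, t = t))
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param m n x 3 coordinate matrix
#' @param fit list with \code{R} and \code{t} as returned by [kabsch()]
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(m, fit) {
  m <- as.matrix(m)
  m %*% t(fit$R) + matrix(fit$t, nrow(m), 3, byrow = TRUE)
}

# RMSD between two coordinate matrices after optimal superposition
superposedRMSD <- function(P, Q) kabsch(P, Q)$rmsd

# residue-order mapping of a template onto an SSE: fragment residue k
# corresponds to the k-th sorted member position
templatePositions <- function(sse) sort(sse@positions)

#' Assemble SSE templates into a full 3D model
#'
#' Starting from the root of the secondary structure tree, each child
#' template is rigidly superposed onto its already-placed parent using all
#' heavy atoms of the base pairs the two elements share (at least three
#' points), then merged; where parent and child both provide an interface
#' residue the parent's copy is kept.  Finally every residue is mutated to
#' the target sequence.
#'
#' @param tree a [SecondaryStructureTree-class]
#' @param chosen list (one entry per SSE, in tree node order) of search
#'   results: each a list with elements \code{template} ([Template-class])
#'   and \code{perfect} (logical); bare [Template-class] objects are
#'   also accepted (treated as perfect)
#' @param targetSeq target nucleotide string (without \code{&})
#' @return list with elements \code{structure} ([NucleicStructure-class]),
#'   \code{perfect} (all SSEs had perfect templates) and \code{provenance}
#'   (per-SSE data.frame: sse, kind, local2d, source, score, perfect)
#' @export
assembleTemplates <- function(tree, chosen, targetSeq) {
  db <- tree@dotbracket
  n <- length(db)
  targetSeq <- toupper(gsub("&", "", targetSeq, fixed = TRUE))
  if (nchar(targetSeq) != n)
    stop("target sequence length does not match the structure")
  letters <- strsplit(targetSeq, "")[[1]]
  sses <- tree@sses
  if (length(chosen) != length(sses))
    stop("need one chosen template per SSE")
  chosen <- lapply(chosen, function(ch) {
    if (is(ch, "Template")) list(template = ch, perfect = TRUE,
                                 score = NA_real_)
    else ch
  })
  for (i in seq_along(sses)) {
    if (is.null(chosen[[i]]) || is.null(chosen[[i]]$template))
      stop("missing template for SSE #", i)
    tpl <- chosen[[i]]$template
    if (nResidues(tpl@fragment) != length(sses[[i]]@positions))
      stop("template size does not fit SSE #", i)
  }
  placed <- vector("list", n)       # per global position: atom data.frame
  placeFragment <- function(i, fit) {
    tpl <- chosen[[i]]$template
    frag <- tpl@fragment
    pos <- templatePositions(sses[[i]])
    for (k in seq_along(pos)) {
      if (!is.null(placed[[pos[k]]])) next        # parent's copy wins
      res <- frag@atoms[frag@atoms$rindex == k, ]
      m <- applyTransform(as.matrix(res[, c("x", "y", "z")]), fit)
      res$x <- m[, 1]; res$y <- m[, 2]; res$z <- m[, 3]
      placed[[pos[k]]] <<- res
    }
  }
  fragCoordsAt <- function(i, gpos) {
    # template-local atoms of SSE i at global position gpos
    tpl <- chosen[[i]]$template
    pos <- templatePositions(sses[[i]])
    k <- match(gpos, pos)
    tpl@fragment@atoms[tpl@fragment@atoms$rindex == k, ]
  }
  identityFit <- list(R = diag(3), t = c(0, 0, 0))
  visited <- rep(FALSE, length(sses))
  roots <- tree@root
  edges <- tree@edges
  allNodes <- seq_along(sses)
  compOffset <- 0
  for (start in c(roots, setdiff(allNodes, roots))) {
    if (visited[start]) next
    # root of a (new) connected component; offset extra components so they
    # do not overlap the already-placed ones
    fit0 <- list(R = diag(3), t = c(compOffset, 0, 0))
    visited[start] <- TRUE
    placeFragment(start, fit0)
    queue <- start
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      kids <- edges$child[edges$parent == u]
      kids <- c(kids, edges$parent[edges$child == u])
      for (v in kids) {
        if (visited[v]) next
        sp <- sharedPairs(sses[[u]], sses[[v]])
        if (!nrow(sp)) next
        iface <- sort(unique(c(sp[, 1], sp[, 2])))
        Pm <- NULL; Qm <- NULL
        for (g in iface) {
          child <- fragCoordsAt(v, g)
          parent <- placed[[g]]
          if (is.null(parent))
            stop("internal error: interface residue not yet placed")
          common <- intersect(child$elety, parent$elety)
          if (!length(common))
            stop(sprintf("no common interface atoms between SSE #%d and #%d",
                         u, v))
          Pm <- rbind(Pm, as.matrix(
            child[match(common, child$elety), c("x", "y", "z")]))
          Qm <- rbind(Qm, as.matrix(
            parent[match(common, parent$elety), c("x", "y", "z")]))
        }
        if (nrow(Pm) < 3L)
          stop(sprintf("interface between SSE #%d and #%d has < 3 atoms",
                       u, v))
        fit <- kabsch(Pm, Qm)
        visited[v] <- TRUE
        placeFragment(v, fit)
        queue <- c(queue, v)
      }
    }
    xs <- unlist(lapply(Filter(Negate(is.null), placed), function(r) r$x))
    compOffset <- max(xs) + 30
  }
  if (any(vapply(placed, is.null, TRUE)))
    stop("unplaced residues after assembly")
  # emit residues in global order with target chain/resno labelling
  ci <- chainIndex(db)
  chains <- LETTERS[ci]
  rows <- list()
  resno <- 0L; lastCh <- ""
  for (g in seq_len(n)) {
    if (chains[g] != lastCh) { resno <- 0L; lastCh <- chains[g] }
    resno <- resno + 1L
    res <- placed[[g]]
    res$chain <- chains[g]; res$resno <- resno; res$inscode <- ""
    rows[[g]] <- res
  }
  a <- do.call(rbind, rows)
  s <- NucleicStructure(a[, c("chain", "resno", "inscode", "resname",
                              "elety", "x", "y", "z")])
  # mutate to the target sequence (deoxy); skip residues already correct
  rt <- residueTable(s)
  for (g in seq_len(n)) {
    want <- letterToDeoxy(letters[g])
    if (rt$resname[g] != want)
      s <- mutateResidueAt(s, g, want)
  }
  perfect <- all(vapply(chosen, function(ch) isTRUE(ch$perfect), TRUE))
  prov <- data.frame(
    sse = seq_along(sses),
    kind = vapply(sses, function(x) x@kind, ""),
    local2d = vapply(sses, function(x) x@local2d, ""),
    source = vapply(chosen, function(ch) ch$template@sourceId, ""),
    score = vapply(chosen, function(ch)
      if (is.null(ch$score)) NA_real_ else as.numeric(ch$score), 1),
    perfect = vapply(chosen, function(ch) isTRUE(ch$perfect), TRUE),
    stringsAsFactors = FALSE)
  list(structure = s, perfect = perfect, provenance = prov)
}

#' Repair chain connectivity by restrained minimization
#'
#' Gradient descent on a harmonic objective: every intra-chain
#' O3'(i)-P(i+1) distance is restrained to 1.60 Angstrom while stiff
#' positional springs hold every atom near its input position, so only the
#' junction neighbourhoods move.  The objective never increases between
#' iterations (backtracking line search); iteration stops at
#' \code{maxIters} or when the gradient norm drops below 1e-6.
#'
#' @param s an assembled [NucleicStructure-class]
#' @param maxIters maximum iterations (default 1000)
#' @param kBond bond-restraint force constant (default 1)
#' @param kPos positional-restraint force constant (default 0.05)
#' @return the repaired [NucleicStructure-class]
#' @export
repairConnectivity <- function(s, maxIters = 1000, kBond = 1, kPos = 0.05) {
  if (maxIters <= 0) return(s)
  a <- s@atoms
  rt <- residueTable(s)
  bonds <- list()
  for (k in seq_len(nrow(rt) - 1L)) {
    if (rt$chain[k] != rt$chain[k + 1L]) next
    i1 <- which(a$rindex == rt$rindex[k] & a$elety == "O3'")
    i2 <- which(a$rindex == rt$rindex[k + 1L] & a$elety == "P")
    if (length(i1) == 1L && length(i2) == 1L)
      bonds[[length(bonds) + 1L]] <- c(i1, i2)
  }
  if (!length(bonds)) return(s)
  B <- do.call(rbind, bonds)
  mob <- sort(unique(as.integer(B)))          # only these atoms can move
  X0 <- as.matrix(a[mob, c("x", "y", "z")])
  Bi <- match(B[, 1], mob); Bj <- match(B[, 2], mob)
  objGrad <- function(X) {
    d <- X[Bi, , drop = FALSE] - X[Bj, , drop = FALSE]
    dist <- sqrt(rowSums(d^2))
    f <- kBond * sum((dist - 1.6)^2) + kPos * sum((X - X0)^2)
    coef <- 2 * kBond * (dist - 1.6) / pmax(dist, 1e-9)
    G <- 2 * kPos * (X - X0)
    gd <- d * coef
    for (r in seq_along(Bi)) {
      G[Bi[r], ] <- G[Bi[r], ] + gd[r, ]
      G[Bj[r], ] <- G[Bj[r], ] - gd[r, ]
    }
    list(f = f, G = G)
  }
  X <- X0
  step <- 0.1
  og <- objGrad(X)
  for (it in seq_len(maxIters)) {
    gn <- sqrt(sum(og$G^2))
    if (gn < 1e-6) break
    repeat {
      Xn <- X - step * og$G
      ogn <- objGrad(Xn)
      if (ogn$f <= og$f || step < 1e-12) break
      step <- step / 2
    }
    if (ogn$f > og$f) break
    X <- Xn; og <- ogn
    step <- step * 1.2
  }
  a$x[mob] <- X[, 1]; a$y[mob] <- X[, 2]; a$z[mob] <- X[, 3]
  initialize(s, atoms = a)
}

# O3'(i)-P(i+1) gap distances across intra-chain junctions
junctionGaps <- function(s) {
  a <- s@atoms
  rt <- residueTable(s)
  gaps <- numeric(0)
  for (k in seq_len(nrow(rt) - 1L)) {
    if (rt$chain[k] != rt$chain[k + 1L]) next
    i1 <- which(a$rindex == rt$rindex[k] & a$elety == "O3'")
    i2 <- which(a$rindex == rt$rindex[k + 1L] & a$elety == "P")
    if (length(i1) == 1L && length(i2) == 1L)
      gaps <- c(gaps, sqrt(sum((as.numeric(a[i1, c("x", "y", "z")]) -
                                as.numeric(a[i2, c("x", "y", "z")]))^2)))
  }
  gaps
}
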