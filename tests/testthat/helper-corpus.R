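# shared synthetic corpus, generated once per test session

.corpusCache <- new.env(parent = emptyenv())

testCorpus <- function() {
  if (is.null(.corpusCache$fx))
    .corpusCache$fx <- generateFixtures(fixtureSpec(defaultFixtureMolecules()))
  .corpusCache$fx
}

testLibrary <- function() {
  if (is.null(.corpusCache$lib)) {
    tpls <- list()
    for (f in testCorpus())
      tpls <- c(tpls, extractTemplates(f$structure, f$db, sourceId = f$id))
    .corpusCache$lib <- templateLibrary(tpls, "dna")
  }
  .corpusCache$lib
}

# random valid single-chain dot-bracket without pseudoknots
randomDotBracketString <- function(n, seed) {
  set.seed(seed)
  gen <- function(len) {
    if (len <= 0) return("")
    if (len < 6 || runif(1) < 0.3) return(strrep(".", len))
    stem <- sample(1:min(4, (len - 2) %/% 2), 1)
    inner <- len - 2 * stem
    pre <- sample(0:min(2, inner), 1)
    paste0(strrep(".", pre), strrep("(", stem),
           gen(inner - pre), strrep(")", stem))
  }
  repeat {
    ss <- gen(n)
    if (nchar(ss) == n) return(ss)
  }
}

# reconstruct the global dot-bracket from an SSE decomposition
reserialize <- function(sses, n) {
  out <- rep(NA_character_, n)
  for (sse in sses) {
    chars <- strsplit(gsub("&", "", sse@local2d, fixed = TRUE), "")[[1]]
    for (k in seq_along(sse@positions)) {
      pos <- sse@positions[k]
      prev <- out[pos]
      if (is.na(prev) || prev == ".") out[pos] <- chars[k]
    }
  }
  paste(out, collapse = "")
}

# brute-force rigid superposition: minimize RMSD over Euler angles after
# centroid alignment (independent oracle for the Kabsch implementation)
bruteForceRMSD <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  rot <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]),
                   0, -sin(a[1]), cos(a[1])), 3, 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3, 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -cos(a[3]) * 0 - sin(a[3]), 
                   cos(a[3]), 0, 0, 0, 1), 3, 3)
    Rz[1, 2] <- -sin(a[3])   # explicit to avoid transcription slips
    Rx %*% Ry %*% Rz
  }
  f <- function(a) sqrt(mean(rowSums((P0 %*% t(rot(a)) - Q0)^2)))
  best <- Inf
  for (sx in seq(0, 2 * pi, length.out = 7)[-7])
    for (sy in seq(0, pi, length.out = 4))
      for (sz in seq(0, 2 * pi, length.out = 7)[-7]) {
        o <- stats::optim(c(sx, sy, sz), f, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-12))
        if (o$value < best) best <- o$value
      }
  best
}
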