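#' Parse an extended dot-bracket string
#'
#' Parses a multi-chain secondary structure written in extended dot-bracket
#' notation: \code{()} for canonical pairs, \code{[]} for pseudoknot pairs,
#' \code{.} for unpaired positions and \code{&} as the chain separator.
#' Pairing follows stack discipline per bracket type.  Global positions are
#' 1-based and do not count the \code{&} characters.
#'
#' @param text dot-bracket string, e.g. \code{"((.&.))"}
#' @return a [DotBracket-class]
#' @examples
#' db <- parseDotBracket("((.&.))")
#' pairTable(db)$pairs   # 6 5 NA NA 2 1
#' @export
parseDotBracket <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("dot-bracket text must be a single non-empty string")
  chars <- strsplit(text, "")[[1]]
  bad <- which(!chars %in% c(".", "(", ")", "[", "]", "&"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]],
                 bad[1]))
  chainStrs <- strsplit(text, "&", fixed = TRUE)[[1]]
  if (grepl("&&", text, fixed = TRUE) || startsWith(text, "&") ||
      endsWith(text, "&") || any(!nzchar(chainStrs)))
    stop("empty chain: leading, trailing or doubled '&'")
  g <- chars[chars != "&"]
  n <- length(g)
  origPos <- which(chars != "&")   # for error messages
  pairs <- rep(NA_integer_, n)
  pkPairs <- rep(NA_integer_, n)
  stackR <- integer(0); stackS <- integer(0)
  for (i in seq_len(n)) {
    c_i <- g[i]
    if (c_i == "(") stackR <- c(stackR, i)
    else if (c_i == "[") stackS <- c(stackS, i)
    else if (c_i == ")") {
      if (!length(stackR))
        stop(sprintf("unbalanced ')' at position %d", origPos[i]))
      j <- stackR[length(stackR)]; stackR <- stackR[-length(stackR)]
      pairs[i] <- j; pairs[j] <- i
    } else if (c_i == "]") {
      if (!length(stackS))
        stop(sprintf("unbalanced ']' at position %d", origPos[i]))
      j <- stackS[length(stackS)]; stackS <- stackS[-length(stackS)]
      pkPairs[i] <- j; pkPairs[j] <- i
    }
  }
  if (length(stackR))
    stop(sprintf("unbalanced '(' at position %d",
                 origPos[stackR[length(stackR)]]))
  if (length(stackS))
    stop(sprintf("unbalanced '[' at position %d",
                 origPos[stackS[length(stackS)]]))
  breakAfter <- cumsum(nchar(chainStrs))
  breakAfter <- as.integer(breakAfter[-length(breakAfter)])
  new("DotBracket", chains = chainStrs, pairs = pairs, pkPairs = pkPairs,
      breakAfter = breakAfter)
}

#' Read a vienna-style secondary structure file
#'
#' Expects an optional \code{>} header line, a sequence line and a structure
#' line.  A bare one-line file is treated as a structure-only file.
#'
#' @param path file path
#' @return list with elements \code{id}, \code{seq} (or \code{NA}) and
#'   \code{ss} (the dot-bracket string)
#' @export
readVienna <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) stop("empty secondary structure file: ", path)
  id <- NA_character_
  if (startsWith(ln[1], ">")) {
    id <- sub("^>\\s*", "", ln[1]); ln <- ln[-1]
  }
  if (length(ln) >= 2L) list(id = id, seq = trimws(ln[1]), ss = trimws(ln[2]))
  else list(id = id, seq = NA_character_, ss = trimws(ln[1]))
}

#' @describeIn DotBracket-class number of nucleotides (global length)
#' @param x a \code{DotBracket}
#' @export
setMethod("length", "DotBracket", function(x) sum(nchar(x@chains)))

#' @describeIn DotBracket-class number of chains
#' @export
setMethod("nChains", "DotBracket", function(x) length(x@chains))

#' Pair table of a DotBracket
#' @param db a [DotBracket-class]
#' @return list with integer vectors \code{pairs} and \code{pkPairs}
#'   (partner position or \code{NA}) and \code{breakAfter}
#' @export
pairTable <- function(db) {
  stopifnot(is(db, "DotBracket"))
  list(pairs = db@pairs, pkPairs = db@pkPairs, breakAfter = db@breakAfter)
}

#' Chain index of each global position
#' @param db a [DotBracket-class]
#' @return integer vector mapping position -> chain number
#' @export
chainIndex <- function(db) {
  n <- length(db)
  idx <- rep(1L, n)
  for (b in db@breakAfter) idx[(b + 1L):n] <- idx[(b + 1L):n] + 1L
  idx
}

setMethod("show", "DotBracket", function(object) {
  cat(sprintf("DotBracket: %d nt, %d chain(s), %d pair(s), %d pk pair(s)\n",
              length(object), nChains(object),
              sum(!is.na(object@pairs)) / 2L,
              sum(!is.na(object@pkPairs)) / 2L))
  cat(" ", paste(object@chains, collapse = "&"), "\n")
})

#' Find all maximal helices
#'
#' A helix (stem) is a maximal run of stacked canonical base pairs: pairs
#' (i, j), (i+1, j-1), ... adjacent on both strands.  Pseudoknot pairs are
#' ignored.
#'
#' @param db a [DotBracket-class]
#' @return list of two-column integer matrices (columns \code{i}, \code{j}),
#'   rows ordered outer to inner; every canonical pair belongs to exactly
#'   one helix
#' @examples
#' length(findHelices(parseDotBracket("((...))")))  # 1
#' @export
findHelices <- function(db) {
  stopifnot(is(db, "DotBracket"))
  p <- db@pairs
  is5 <- which(!is.na(p) & p > seq_along(p))
  if (!length(is5)) return(list())
  is5 <- sort(is5)
  helices <- list()
  cur <- NULL
  for (i in is5) {
    j <- p[i]
    if (!is.null(cur) && cur[nrow(cur), 1L] == i - 1L &&
        cur[nrow(cur), 2L] == j + 1L) {
      cur <- rbind(cur, c(i, j))
    } else {
      if (!is.null(cur)) helices[[length(helices) + 1L]] <- cur
      cur <- matrix(c(i, j), 1L, 2L)
    }
  }
  helices[[length(helices) + 1L]] <- cur
  lapply(helices, function(m) {
    colnames(m) <- c("i", "j"); storage.mode(m) <- "integer"; m
  })
}

# render the local dot-bracket of a member set, inserting '&' where a chain
# break falls between adjacent member positions
renderLocal <- function(positions, pairsMat, db) {
  op <- if (nrow(pairsMat)) pairsMat[, 1L] else integer(0)
  cl <- if (nrow(pairsMat)) pairsMat[, 2L] else integer(0)
  out <- character(0)
  for (k in seq_along(positions)) {
    pos <- positions[k]
    ch <- if (pos %in% op) "(" else if (pos %in% cl) ")" else "."
    out <- c(out, ch)
    if (k < length(positions) && positions[k + 1L] == pos + 1L &&
        pos %in% db@breakAfter)
      out <- c(out, "&")
  }
  paste(out, collapse = "")
}

makeSSE <- function(id, kind, positions, pairsMat, db, seq = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (!nrow(pairsMat)) {
    pairsMat <- matrix(integer(0), 0L, 2L)
  } else {
    pairsMat <- pairsMat[order(pairsMat[, 1L]), , drop = FALSE]
  }
  colnames(pairsMat) <- c("i", "j")
  localSeq <- if (is.null(seq)) NA_character_ else
    paste(strsplit(seq, "")[[1]][positions], collapse = "")
  new("SSE", id = as.integer(id), kind = kind, positions = positions,
      pairs = pairsMat, local2d = renderLocal(positions, pairsMat, db),
      localSeq = localSeq)
}

#' Decompose a secondary structure into smallest secondary elements
#'
#' Cuts the structure into stems and loop elements.  Each maximal helix
#' becomes a stem; each loop region bounded by helix ends becomes a loop
#' element of kind hairpin (closed by one helix end), bulge / internal
#' (two helix ends with one / both intervening unpaired segments non-empty),
#' junction (three or more helix ends), open (exterior region holding the
#' molecule's dangling termini) or break (a helix end whose two strands are
#' separated by a chain break).  Loop elements carry \code{min(2, helix
#' length)} boundary pairs from each adjoining helix.  Pseudoknot pairs are
#' treated as unpaired.
#'
#' @param db a [DotBracket-class]
#' @param seq optional nucleotide string of the same length, used to fill
#'   \code{localSeq}
#' @return list of [SSE-class], ordered by first member position
#' @examples
#' sses <- decomposeSSE(parseDotBracket("((...))"))
#' vapply(sses, function(s) s@kind, "")   # "stem" "hairpin"
#' @export
decomposeSSE <- function(db, seq = NULL) {
  stopifnot(is(db, "DotBracket"))
  n <- length(db)
  if (!is.null(seq)) {
    seq <- toupper(gsub("&", "", seq, fixed = TRUE))
    if (nchar(seq) != n) stop("sequence length does not match structure")
  }
  p <- db@pairs
  helices <- findHelices(db)
  if (!length(helices)) {
    sse <- makeSSE(1L, "open", seq_len(n), matrix(integer(0), 0, 2), db, seq)
    return(list(sse))
  }
  helixOf <- rep(NA_integer_, n)
  for (h in seq_along(helices))
    helixOf[c(helices[[h]][, 1L], helices[[h]][, 2L])] <- h
  bounds <- function(h, side, k) {
    # k boundary pairs of helix h: side "inner" = innermost, "outer"
    m <- helices[[h]]
    k <- min(k, nrow(m))
    if (side == "inner") m[(nrow(m) - k + 1L):nrow(m), , drop = FALSE]
    else m[seq_len(k), , drop = FALSE]
  }
  out <- list()
  # stems
  for (h in seq_along(helices)) {
    m <- helices[[h]]
    out[[length(out) + 1L]] <-
      makeSSE(0L, "stem", c(m[, 1L], m[, 2L]), m, db, seq)
  }
  # enclosed loops: one candidate region per helix, inside its inner pair
  for (h in seq_along(helices)) {
    m <- helices[[h]]
    a <- m[nrow(m), 1L]; b <- m[nrow(m), 2L]
    if (b - a <= 1L && !any(db@breakAfter >= a & db@breakAfter < b)) next
    children <- integer(0)
    unpaired <- integer(0)
    segs <- list(); cur <- integer(0)
    t <- a + 1L
    while (t < b) {
      if (!is.na(p[t])) {
        children <- c(children, helixOf[t])
        segs[[length(segs) + 1L]] <- cur; cur <- integer(0)
        t <- p[t] + 1L
      } else {
        cur <- c(cur, t); unpaired <- c(unpaired, t)
        t <- t + 1L
      }
    }
    segs[[length(segs) + 1L]] <- cur
    childSpan <- function(hc) {
      mm <- helices[[hc]]; c(mm[1L, 1L], mm[1L, 2L])
    }
    bk <- db@breakAfter[db@breakAfter >= a & db@breakAfter < b]
    for (hc in children) {
      sp <- childSpan(hc)
      bk <- bk[!(bk >= sp[1L] & bk < sp[2L])]
    }
    nchild <- length(children)
    if (!length(unpaired) && !nchild && !length(bk)) next
    kind <- if (nchild == 0L) {
      if (length(bk)) "break" else "hairpin"
    } else if (nchild == 1L) {
      if (all(lengths(segs) > 0L)) "internal" else "bulge"
    } else "junction"
    pm <- bounds(h, "inner", 2L)
    for (hc in children) pm <- rbind(pm, bounds(hc, "outer", 2L))
    out[[length(out) + 1L]] <-
      makeSSE(0L, kind, c(unpaired, pm[, 1L], pm[, 2L]), pm, db, seq)
  }
  # exterior region(s): positions and helices not enclosed by any pair,
  # connected along the strand, cut at chain breaks
  enclosed <- rep(FALSE, n)
  topHelices <- integer(0)
  t <- 1L
  entities <- list()   # list of list(type, span)
  while (t <= n) {
    if (!is.na(p[t]) && p[t] > t) {
      topHelices <- c(topHelices, helixOf[t])
      entities[[length(entities) + 1L]] <-
        list(type = "helix", h = helixOf[t], span = c(t, p[t]))
      t <- p[t] + 1L
    } else {
      entities[[length(entities) + 1L]] <-
        list(type = "pos", span = c(t, t))
      t <- t + 1L
    }
  }
  # union-find over entities; adjacent entities joined unless a break
  # separates them
  parent <- seq_along(entities)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(length(entities) - 1L)) {
    boundary <- entities[[k]]$span[2L]
    if (!boundary %in% db@breakAfter)
      parent[findp(k + 1L)] <- findp(k)
  }
  comp <- vapply(seq_along(entities), findp, 1L)
  for (cid in unique(comp)) {
    es <- entities[comp == cid]
    posMembers <- unlist(lapply(es, function(e)
      if (e$type == "pos") e$span[1L] else integer(0)))
    hs <- unlist(lapply(es, function(e)
      if (e$type == "helix") e$h else integer(0)))
    if (!length(posMembers) && length(hs) <= 1L) next
    pm <- matrix(integer(0), 0L, 2L)
    for (hh in hs) pm <- rbind(pm, bounds(hh, "outer", 2L))
    out[[length(out) + 1L]] <-
      makeSSE(0L, "open", c(posMembers, pm[, 1L], pm[, 2L]), pm, db, seq)
  }
  out <- out[order(vapply(out, function(s) s@positions[1L], 1L),
                   vapply(out, function(s) s@kind != "open", TRUE))]
  for (i in seq_along(out)) out[[i]]@id <- i
  out
}

#' @describeIn topologyKey key of a bare local dot-bracket string
#' @export
setMethod("topologyKey", "character", function(x) x)

#' @describeIn topologyKey key of an SSE
#' @export
setMethod("topologyKey", "SSE", function(x) x@local2d)

#' @describeIn topologyKey key of a Template
#' @export
setMethod("topologyKey", "Template", function(x) x@local2d)

setMethod("show", "SSE", function(object) {
  cat(sprintf("SSE #%d <%s> %s  [%d nt, %d pair(s)]\n", object@id,
              object@kind, object@local2d, length(object@positions),
              nrow(object@pairs)))
})

sharedPairs <- function(s1, s2) {
  a <- s1@pairs; b <- s2@pairs
  if (!nrow(a) || !nrow(b)) return(matrix(integer(0), 0L, 2L))
  keep <- paste(a[, 1L], a[, 2L]) %in% paste(b[, 1L], b[, 2L])
  a[keep, , drop = FALSE]
}

#' Build the secondary structure tree from a decomposition
#'
#' Connects each stem to the loop elements it shares boundary base pairs
#' with; adjoining elements share \code{min(2, helix length)} common pairs,
#' which later serve as the superposition interface during assembly.  The
#' root is the element containing the global 5' terminus (the open loop if
#' one exists there, else the outermost stem).  Disconnected components
#' each get their own subtree, rooted at their first element.
#'
#' @param sses list of [SSE-class] from [decomposeSSE()]
#' @param db the [DotBracket-class] they were derived from
#' @return a [SecondaryStructureTree-class]
#' @export
buildSST <- function(sses, db) {
  stopifnot(length(sses) >= 1L)
  nN <- length(sses)
  kinds <- vapply(sses, function(s) s@kind, "")
  adj <- vector("list", nN)
  for (i in which(kinds == "stem")) {
    for (j in which(kinds != "stem")) {
      sp <- sharedPairs(sses[[i]], sses[[j]])
      if (nrow(sp)) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  hasPos1 <- vapply(sses, function(s) 1L %in% s@positions, TRUE)
  root <- if (any(hasPos1 & kinds != "stem")) which(hasPos1 & kinds != "stem")[1L]
          else which(hasPos1)[1L]
  visited <- rep(FALSE, nN)
  parentOf <- rep(NA_integer_, nN)
  edges <- data.frame(parent = integer(0), child = integer(0))
  order0 <- c(root, setdiff(seq_len(nN), root))
  for (start in order0) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          parentOf[v] <- u
          edges <- rbind(edges, data.frame(parent = u, child = v))
          queue <- c(queue, v)
        }
      }
    }
  }
  new("SecondaryStructureTree", sses = sses, edges = edges,
      root = as.integer(root), dotbracket = db)
}

#' @describeIn SecondaryStructureTree-class list of SSE nodes
#' @param tree a \code{SecondaryStructureTree}
#' @export
treeSSEs <- function(tree) tree@sses

#' @describeIn SecondaryStructureTree-class edge table (parent, child)
#' @export
treeEdges <- function(tree) tree@edges

#' @describeIn SecondaryStructureTree-class index of the root node
#' @export
treeRoot <- function(tree) tree@root

setMethod("show", "SecondaryStructureTree", function(object) {
  kinds <- vapply(object@sses, function(s) s@kind, "")
  cat(sprintf("SecondaryStructureTree: %d node(s), %d edge(s), root #%d\n",
              length(object@sses), nrow(object@edges), object@root))
  cat("  kinds:", paste(sprintf("%s#%d", kinds, seq_along(kinds)),
                        collapse = " "), "\n")
})
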