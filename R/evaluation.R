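## Evaluation (all-atom RMSD with and without open loops), the synthetic
## fixture corpus generator, and the end-to-end prediction pipeline.

#' All-atom RMSD between a prediction and a native structure
#'
#' Residues are matched one-to-one in order (an error lists the first
#' divergence if counts or residue names differ); atoms are intersected by
#' name within each residue and the RMSD is minimized by Kabsch
#' superposition.  When a secondary structure tree is supplied, a second
#' RMSD is computed with the unpaired nucleotides of open-kind SSEs
#' removed from both structures (boundary base pairs retained), the
#' "no open loop" convention for flexible dangling ends.
#'
#' @param pred predicted [NucleicStructure-class]
#' @param native reference [NucleicStructure-class]
#' @param tree optional [SecondaryStructureTree-class] of the target
#' @return list with \code{rmsdAll}, \code{rmsdNoOpen} (NA without a
#'   tree), \code{nAtomsAll}, \code{nAtomsNoOpen}, \code{nOpenRemoved}
#' @export
evaluateRMSD <- function(pred, native, tree = NULL) {
  cp <- residueCodes(pred)
  cn <- residueCodes(native)
  if (length(cp) != length(cn))
    stop(sprintf("residue count mismatch: %d vs %d", length(cp),
                 length(cn)))
  div <- which(cp != cn)
  if (length(div))
    stop(sprintf("residue mismatch at position %d: %s vs %s", div[1],
                 cp[div[1]], cn[div[1]]))
  matched <- function(excluded = integer(0)) {
    P <- NULL; Q <- NULL
    for (k in seq_along(cp)) {
      if (k %in% excluded) next
      mp <- residueCoords(pred, k)
      mq <- residueCoords(native, k)
      common <- intersect(rownames(mp), rownames(mq))
      P <- rbind(P, mp[common, , drop = FALSE])
      Q <- rbind(Q, mq[common, , drop = FALSE])
    }
    list(P = P, Q = Q)
  }
  mAll <- matched()
  rmsdAll <- kabsch(mAll$P, mAll$Q)$rmsd
  rmsdNoOpen <- NA_real_; nNoOpen <- NA_integer_; nRemoved <- 0L
  if (!is.null(tree)) {
    excl <- integer(0)
    for (sse in tree@sses) {
      if (sse@kind != "open") next
      paired <- if (nrow(sse@pairs)) c(sse@pairs[, 1], sse@pairs[, 2])
                else integer(0)
      excl <- c(excl, setdiff(sse@positions, paired))
    }
    excl <- sort(unique(excl))
    nRemoved <- length(excl)
    mNo <- matched(excl)
    if (is.null(mNo$P) || nrow(mNo$P) < 3L)
      stop("too few atoms left after removing open loops")
    rmsdNoOpen <- kabsch(mNo$P, mNo$Q)$rmsd
    nNoOpen <- nrow(mNo$P)
  }
  list(rmsdAll = rmsdAll, rmsdNoOpen = rmsdNoOpen,
       nAtomsAll = nrow(mAll$P), nAtomsNoOpen = nNoOpen,
       nOpenRemoved = nRemoved)
}

#' Select the best structure per the perfect-template rule
#'
#' When every SSE had a perfect template the assembled structure is the
#' final (best) structure; otherwise the top-ranked optimized structure is
#' chosen (falling back to the assembly, with a warning, when no optimized
#' structures exist).
#'
#' @param assembled the assembled [NucleicStructure-class]
#' @param optimizedList list from [clusterAndRank()] (possibly empty)
#' @param perfect logical: did all SSEs have perfect templates?
#' @return a [NucleicStructure-class]
#' @export
selectBest <- function(assembled, optimizedList, perfect) {
  if (perfect) return(assembled)
  if (length(optimizedList)) return(optimizedList[[1]]$structure)
  warning("no optimized structures; returning the assembled structure")
  assembled
}

#' Specification for a synthetic fixture corpus
#'
#' @param molecules list of molecules, each a list with \code{id},
#'   \code{ss} (extended dot-bracket) and \code{seq} (nucleotides, same
#'   length, \code{&} optional)
#' @param noiseSigma Gaussian coordinate noise in Angstrom (default 0)
#' @param seed RNG seed for the noise (default 1)
#' @param twist,rise helix parameters (degrees per bp / Angstrom per bp;
#'   canonical B-DNA fiber defaults 36 and 3.38)
#' @return a validated specification list
#' @export
fixtureSpec <- function(molecules, noiseSigma = 0, seed = 1,
                        twist = 36, rise = 3.38) {
  stopifnot(noiseSigma >= 0, length(molecules) >= 1)
  for (m in molecules)
    stopifnot(!is.null(m$id), !is.null(m$ss), !is.null(m$seq))
  list(molecules = molecules, noiseSigma = noiseSigma, seed = seed,
       twist = twist, rise = rise)
}

#' Generate a synthetic corpus of idealized structures
#'
#' Each molecule's secondary structure is decomposed, every SSE is built
#' from ideal geometry (B-form helices, smooth-arc loops) and the
#' fragments are assembled into a full all-atom model; optional Gaussian
#' coordinate noise is added.  Deterministic for a given seed.  Generated
#' structures clean, complete and coarse-grain without errors and
#' decompose back to the specified dot-brackets.
#'
#' @param spec a [fixtureSpec()]
#' @return list of entries, each with \code{id}, \code{structure}
#'   ([NucleicStructure-class]), \code{db} ([DotBracket-class]) and
#'   \code{seq}
#' @export
generateFixtures <- function(spec) {
  set.seed(spec$seed)
  out <- list()
  for (mol in spec$molecules) {
    db <- parseDotBracket(mol$ss)
    seq <- toupper(gsub("&", "", mol$seq, fixed = TRUE))
    if (nchar(seq) != length(db))
      stop("sequence/structure length mismatch for ", mol$id)
    sses <- decomposeSSE(db, seq)
    tree <- buildSST(sses, db)
    chosen <- lapply(sses, function(s)
      list(template = buildFallback(s, s@localSeq, twist = spec$twist,
                                    rise = spec$rise),
           perfect = TRUE, score = NA_real_))
    asm <- assembleTemplates(tree, chosen, seq)
    s <- asm$structure
    if (spec$noiseSigma > 0) {
      a <- s@atoms
      a$x <- a$x + stats::rnorm(nrow(a), 0, spec$noiseSigma)
      a$y <- a$y + stats::rnorm(nrow(a), 0, spec$noiseSigma)
      a$z <- a$z + stats::rnorm(nrow(a), 0, spec$noiseSigma)
      s <- initialize(s, atoms = a)
    }
    out[[length(out) + 1L]] <- list(id = mol$id, structure = s, db = db,
                                    seq = seq)
  }
  out
}

# deterministic WC-consistent sequence for a dot-bracket structure
randomSequenceFor <- function(ss, seed) {
  db <- parseDotBracket(ss)
  set.seed(seed)
  n <- length(db)
  letters4 <- c("A", "C", "G", "T")
  seq <- sample(letters4, n, replace = TRUE)
  p <- db@pairs
  for (i in seq_len(n)) {
    j <- p[i]
    if (!is.na(j) && j > i) seq[j] <- COMPLEMENT_DNA[[seq[i]]]
  }
  paste(seq, collapse = "")
}

#' Default synthetic corpus: the molecules used throughout the test suite
#'
#' Fourteen molecules emulating the composition of the template corpus:
#' single-chain hairpins with and without dangling open loops, bulge and
#' internal loops, three-way junctions, and double-chain molecules with
#' break loops (including a two-chain open/bulge/break architecture).
#' Each topology appears twice with different (Watson-Crick consistent)
#' sequences so that leave-one-out searches still find a same-topology
#' template.
#'
#' @param seed seed for the deterministic sequence assignment (default 1)
#' @return list of molecules suitable for [fixtureSpec()]
#' @export
defaultFixtureMolecules <- function(seed = 1) {
  topologies <- c(
    ".((((....)))).",
    "((((.....))))",
    ".(((((.....(((((.&.)))))))))).",
    "(((..((((....)))).)))",
    "((((....&..))))",
    "((..((...))..((...))..))",
    "((((((..((((....))))))))))")
  mols <- list()
  k <- 0L
  for (ti in seq_along(topologies)) {
    for (rep in 1:2) {
      k <- k + 1L
      mols[[k]] <- list(id = sprintf("FIX%02d", k), ss = topologies[ti],
                        seq = randomSequenceFor(topologies[ti],
                                                seed + 97L * k))
    }
  }
  mols
}

#' Run the full prediction pipeline
#'
#' Decompose, search templates (with exclusions), assemble, repair chain
#' connectivity and, when the templates are not all perfect, refine by
#' SAMC and cluster to at most \code{nOut} optimized structures; the best
#' structure follows the perfect-template selection rule.
#'
#' @param seq target sequence (may contain \code{&})
#' @param ss target secondary structure in extended dot-bracket
#' @param dnaLib the DNA [TemplateLibrary-class]
#' @param rnaLib optional RNA [TemplateLibrary-class]
#' @param exclude source ids to exclude from the search
#' @param em optional trained [EnergyModel-class]; trained from
#'   \code{dnaLib} on demand when refinement is needed
#' @param cfg [samcConfig()] for the refinement stage
#' @param nOut maximum number of optimized structures (default 5)
#' @param skipOptimize skip the refinement stage
#' @param outPrefix when set, write \code{<prefix>_assembled.pdb},
#'   \code{<prefix>_opt_<i>.pdb} and \code{<prefix>_report.tsv}
#' @param verbose log each stage
#' @return list with \code{assembled}, \code{optimized} (list of
#'   structure+energy), \code{best}, \code{perfect}, \code{provenance},
#'   \code{tree}
#' @export
runPipeline <- function(seq, ss, dnaLib, rnaLib = NULL,
                        exclude = character(), em = NULL,
                        cfg = samcConfig(), nOut = 5,
                        skipOptimize = FALSE, outPrefix = NULL,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[dnassembly] ", ...)
  db <- parseDotBracket(ss)
  seqc <- toupper(gsub("[&[:space:]]", "", seq))
  if (nchar(seqc) != length(db))
    stop("sequence and secondary structure differ in length")
  say("decomposing: ", length(db), " nt, ", nChains(db), " chain(s)")
  sses <- decomposeSSE(db, seqc)
  tree <- buildSST(sses, db)
  say(length(sses), " SSE(s): ",
      paste(vapply(sses, function(s) s@kind, ""), collapse = " "))
  chosen <- lapply(sses, function(s)
    searchTemplate(s, dnaLib, rnaLib, exclude))
  say("templates: ",
      sum(vapply(chosen, function(ch) ch$perfect, TRUE)), "/",
      length(chosen), " perfect")
  asm <- assembleTemplates(tree, chosen, seqc)
  say("assembled; repairing connectivity")
  repaired <- repairConnectivity(asm$structure)
  optimized <- list()
  if (!asm$perfect && !skipOptimize) {
    if (is.null(em)) {
      say("training statistical potential from the DNA library")
      em <- trainPotential(dnaLib)
    }
    say("refining by SAMC (", cfg$nSteps, " proposals)")
    samc <- samcOptimize(repaired, tree, em, cfg)
    optimized <- clusterAndRank(samc, repaired, k = nOut)
    say(length(optimized), " optimized structure(s)")
  }
  best <- selectBest(repaired, optimized, asm$perfect)
  if (!is.null(outPrefix)) {
    writeStructure(repaired, paste0(outPrefix, "_assembled.pdb"))
    for (i in seq_along(optimized))
      writeStructure(optimized[[i]]$structure,
                     sprintf("%s_opt_%d.pdb", outPrefix, i))
    rep <- asm$provenance
    names(rep) <- c("sse_id", "kind", "local_2d", "template_source",
                    "score", "perfect")
    utils::write.table(rep, paste0(outPrefix, "_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(assembled = repaired, optimized = optimized, best = best,
       perfect = asm$perfect, provenance = asm$provenance, tree = tree)
}
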