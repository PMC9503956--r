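## SSE 3D template library: corpus filtering, template extraction, topology
## indexing, match scoring, search with RNA fallback and a de novo
## ideal-geometry builder, plus the on-disk library format (a directory of
## fragment PDB files and a tab-separated index).

#' Classify a corpus structure and decide whether to keep it
#'
#' Structures are classed from their secondary structure: no canonical
#' pairs -> \code{unStru}; every nucleotide in a canonical pair ->
#' \code{Helix} (pure duplex); otherwise \code{D} (duplex plus loops).
#' Triplex (\code{T}) and quadruplex (\code{G}) detection is outside the
#' scope of the secondary-structure input and is honoured only through the
#' optional user annotation.  Only class-D structures with at least 4
#' nucleotides are kept for the template library.
#'
#' @param s the (standardized) [NucleicStructure-class]
#' @param db the matching [DotBracket-class]
#' @param annotatedClass optional user annotation \code{"T"} or \code{"G"}
#' @return list with elements \code{keep} (logical) and \code{label}
#' @export
corpusFilter <- function(s, db, annotatedClass = NA_character_) {
  if (nResidues(s) != length(db))
    stop("structure and secondary structure differ in length")
  label <- if (!is.na(annotatedClass) && annotatedClass %in% c("T", "G"))
    annotatedClass
  else if (!any(!is.na(db@pairs))) "unStru"
  else if (all(!is.na(db@pairs))) "Helix"
  else "D"
  list(keep = label == "D" && length(db) >= 4L, label = label)
}

# rebuild a fragment structure from member residues of a source structure;
# residues renumbered 1..m with chains split at the member-local breaks
extractFragment <- function(s, positions, db) {
  a <- s@atoms
  ci <- chainIndex(db)[positions]
  chains <- LETTERS[match(ci, unique(ci))]
  rows <- list()
  resno <- 0L; lastCh <- ""
  for (k in seq_along(positions)) {
    res <- a[a$rindex == positions[k], ]
    if (!nrow(res)) return(NULL)
    if (chains[k] != lastCh) { resno <- 0L; lastCh <- chains[k] }
    resno <- resno + 1L
    res$chain <- chains[k]; res$resno <- resno; res$inscode <- ""
    rows[[k]] <- res
  }
  a2 <- do.call(rbind, rows)
  NucleicStructure(a2[, c("chain", "resno", "inscode", "resname", "elety",
                          "x", "y", "z")])
}

#' Cut a corpus structure into SSE templates
#'
#' Decomposes the structure's secondary structure and copies the member
#' residues of every SSE into a [Template-class] fragment.  Residues with
#' missing coordinates cause that template to be skipped (with a message).
#'
#' @param s the standardized [NucleicStructure-class] (residue i must
#'   correspond to secondary structure position i)
#' @param db the matching [DotBracket-class]
#' @param sourceId identifier recorded on the templates
#' @param sourceKind \code{"dna"} or \code{"rna"}
#' @param resolution resolution in Angstrom or NA
#' @return list of [Template-class]
#' @export
extractTemplates <- function(s, db, sourceId = "anon", sourceKind = "dna",
                             resolution = NA_real_) {
  if (nResidues(s) != length(db))
    stop("structure and secondary structure differ in length")
  seq <- paste(residueCodes(s), collapse = "")
  sses <- decomposeSSE(db, seq)
  out <- list()
  for (sse in sses) {
    frag <- extractFragment(s, sse@positions, db)
    if (is.null(frag)) {
      message("skipping template for SSE #", sse@id,
              ": residue missing coordinates")
      next
    }
    out[[length(out) + 1L]] <- new("Template", sseKind = sse@kind,
      local2d = sse@local2d, localSeq = sse@localSeq, fragment = frag,
      sourceId = sourceId, sourceKind = sourceKind,
      resolution = as.numeric(resolution))
  }
  out
}

libKey <- function(kind, local2d) paste0(kind, "|", local2d)

#' Build a template library from a list of templates
#' @param templates list of [Template-class]
#' @param kind library kind, \code{"dna"} or \code{"rna"}
#' @return a [TemplateLibrary-class]
#' @export
templateLibrary <- function(templates, kind = "dna") {
  index <- list()
  for (i in seq_along(templates)) {
    key <- libKey(templates[[i]]@sseKind, templates[[i]]@local2d)
    index[[key]] <- c(index[[key]], i)
  }
  new("TemplateLibrary", templates = templates, index = index, kind = kind)
}

#' @describeIn TemplateLibrary-class template counts by SSE kind
#' @param lib a \code{TemplateLibrary}
#' @export
templateCounts <- function(lib) {
  kinds <- vapply(lib@templates, function(t) t@sseKind, "")
  table(factor(kinds, levels = c("stem", "hairpin", "bulge", "internal",
                                 "junction", "open", "break")))
}

setMethod("show", "TemplateLibrary", function(object) {
  cat(sprintf("TemplateLibrary (%s): %d template(s), %d topology key(s)\n",
              object@kind, length(object@templates), length(object@index)))
})

setMethod("show", "Template", function(object) {
  cat(sprintf("Template <%s> %s [%s] from %s (%s)\n", object@sseKind,
              object@local2d, object@localSeq, object@sourceId,
              object@sourceKind))
})

#' Score a template against a query SSE
#'
#' Five points when the secondary structure topology (local dot-bracket
#' string, including \code{&} placement) is identical, zero otherwise;
#' then, traversing the sequence, one point per matching nucleotide in the
#' loop region and 0.2 points per matching nucleotide in the helix region.
#' Sequence points are only counted when query and template sequences have
#' equal length.
#'
#' @param query2d local dot-bracket of the query SSE
#' @param querySeq local sequence of the query SSE
#' @param template a [Template-class]
#' @return list with \code{topologyPoints}, \code{loopMatches},
#'   \code{helixMatches} and \code{total}
#' @examples
#' # identical topology and sequence: 5 + |loop| + 0.2 |helix|
#' @export
scoreMatch <- function(query2d, querySeq, template) {
  topo <- if (identical(query2d, template@local2d)) 5 else 0
  loopM <- 0L; helixM <- 0L
  qs <- strsplit(toupper(querySeq), "")[[1]]
  ts <- strsplit(toupper(template@localSeq), "")[[1]]
  if (length(qs) == length(ts) && length(qs)) {
    q2 <- strsplit(gsub("&", "", query2d, fixed = TRUE), "")[[1]]
    if (length(q2) == length(qs)) {
      same <- qs == ts
      loopMask <- q2 == "."
      loopM <- sum(same & loopMask)
      helixM <- sum(same & !loopMask)
    }
  }
  list(topologyPoints = topo, loopMatches = loopM, helixMatches = helixM,
       total = topo + 1.0 * loopM + 0.2 * helixM)
}

# convert a ribo fragment to deoxy: U -> DT (gains C7), A/C/G -> DA/DC/DG
# (2'-OH removed); deoxy residues pass through
riboToDeoxy <- function(frag) {
  rt <- residueTable(frag)
  for (k in seq_len(nrow(rt))) {
    rn <- rt$resname[k]
    if (rn %in% STANDARD_RNA)
      frag <- mutateResidueAt(frag, k,
                              letterToDeoxy(BASE_LETTER[[rn]]))
  }
  frag
}

#' Search the template libraries for the best-scoring SSE template
#'
#' Candidates with the same topology key are ranked by the match score;
#' ties are broken by preferring DNA sources over RNA, better (smaller)
#' resolution, then lexicographic source id.  When the DNA library has no
#' same-topology candidate the RNA library is searched (its fragment is
#' converted U to T); when neither has one, a de novo ideal-geometry
#' template is built.  A search result is "perfect" only when it comes
#' from the DNA library with matching topology.
#'
#' @param sse the query [SSE-class] (its \code{localSeq} must be set)
#' @param dnaLib a [TemplateLibrary-class]
#' @param rnaLib optional RNA [TemplateLibrary-class]
#' @param exclude character vector of source ids to exclude (e.g. the test
#'   set a target belongs to)
#' @return list with \code{template}, \code{perfect} (flag) and
#'   \code{score}
#' @export
searchTemplate <- function(sse, dnaLib, rnaLib = NULL,
                           exclude = character()) {
  querySeq <- sse@localSeq
  if (is.na(querySeq)) stop("query SSE carries no sequence")
  key <- libKey(sse@kind, sse@local2d)
  pickBest <- function(lib) {
    idx <- lib@index[[key]]
    if (is.null(idx)) return(NULL)
    idx <- idx[!vapply(idx, function(i)
      lib@templates[[i]]@sourceId %in% exclude, TRUE)]
    if (!length(idx)) return(NULL)
    scores <- lapply(idx, function(i)
      scoreMatch(sse@local2d, querySeq, lib@templates[[i]]))
    totals <- vapply(scores, function(sc) sc$total, 1)
    res <- vapply(idx, function(i) {
      r <- lib@templates[[i]]@resolution
      if (is.na(r)) Inf else r
    }, 1)
    ids <- vapply(idx, function(i) lib@templates[[i]]@sourceId, "")
    ord <- order(-totals, res, ids)
    list(template = lib@templates[[idx[ord[1]]]],
         score = totals[ord[1]])
  }
  hit <- pickBest(dnaLib)
  if (!is.null(hit))
    return(list(template = hit$template, perfect = TRUE, score = hit$score))
  if (!is.null(rnaLib)) {
    hit <- pickBest(rnaLib)
    if (!is.null(hit)) {
      tpl <- hit$template
      frag <- riboToDeoxy(tpl@fragment)
      seq <- paste(residueCodes(frag), collapse = "")
      tpl <- new("Template", sseKind = tpl@sseKind, local2d = tpl@local2d,
                 localSeq = seq, fragment = frag, sourceId = tpl@sourceId,
                 sourceKind = "rna", resolution = tpl@resolution)
      return(list(template = tpl, perfect = FALSE, score = hit$score))
    }
  }
  tpl <- buildFallback(sse, querySeq)
  list(template = tpl, perfect = FALSE, score = 0)
}

#' Build a de novo template from ideal geometry
#'
#' Helix regions are built as an ideal B-form duplex (36 degree twist,
#' 3.38 Angstrom rise per base pair); unpaired loop nucleotides are placed
#' on a smooth circular arc connecting the attachment backbone atoms.
#'
#' @param sse the [SSE-class] to template
#' @param seq local nucleotide string (defaults to the SSE's own)
#' @param twist,rise helix parameters (defaults 36 degrees / 3.38 Angstrom
#'   per bp)
#' @return a [Template-class] with \code{sourceKind = "denovo"}
#' @export
buildFallback <- function(sse, seq = sse@localSeq, twist = 36,
                          rise = 3.38) {
  if (is.na(seq)) stop("no sequence for de novo template")
  localDb <- parseDotBracket(sse@local2d)
  m <- length(localDb)
  pt <- localDb@pairs
  p5 <- which(!is.na(pt) & pt > seq_len(m))
  pm <- cbind(i = p5, j = pt[p5])
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  storage.mode(pm) <- "integer"
  localSse <- new("SSE", id = 1L, kind = sse@kind,
                  positions = seq_len(m), pairs = pm,
                  local2d = sse@local2d, localSeq = seq)
  letters <- strsplit(toupper(seq), "")[[1]]
  frag <- buildIdealFragment(localSse, letters, localDb, twist, rise)
  new("Template", sseKind = sse@kind, local2d = sse@local2d,
      localSeq = paste(letters, collapse = ""), fragment = frag,
      sourceId = "denovo", sourceKind = "denovo",
      resolution = NA_real_)
}

#' Save a template library to a directory
#'
#' The on-disk format is a directory of fragment PDB files plus one
#' tab-separated index (\code{index.tsv}: source_id, kind, local_2d,
#' local_seq, resolution, file).
#'
#' @param lib a [TemplateLibrary-class]
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
saveLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(source_id = character(), kind = character(),
                    local_2d = character(), local_seq = character(),
                    resolution = numeric(), file = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lib@templates)) {
    t <- lib@templates[[i]]
    f <- sprintf("frag_%05d.pdb", i)
    writeStructure(t@fragment, file.path(dir, f))
    idx[i, ] <- list(t@sourceId, t@sseKind, t@local2d, t@localSeq,
                     t@resolution, f)
  }
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a template library from a directory
#' @param dir directory written by [saveLibrary()]
#' @param kind library kind, \code{"dna"} or \code{"rna"}
#' @return a [TemplateLibrary-class]
#' @export
loadLibrary <- function(dir, kind = "dna") {
  idx <- utils::read.delim(file.path(dir, "index.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(local_2d = "character",
                                          local_seq = "character"))
  templates <- lapply(seq_len(nrow(idx)), function(i) {
    frag <- readStructure(file.path(dir, idx$file[i]))
    new("Template", sseKind = idx$kind[i], local2d = idx$local_2d[i],
        localSeq = idx$local_seq[i], fragment = frag,
        sourceId = idx$source_id[i],
        sourceKind = kind, resolution = as.numeric(idx$resolution[i]))
  })
  templateLibrary(templates, kind)
}

#' Build a template library from a corpus manifest
#'
#' The manifest is a data.frame (or TSV path) with columns
#' \code{pdb_path}, \code{dotbracket_path}, \code{id} and
#' \code{resolution}.  Each entry is read, cleaned and standardized,
#' completed, filtered (class D, length >= 4, exact duplicates by sequence
#' plus secondary structure removed) and cut into SSE templates.
#'
#' @param manifest data.frame or path to a tab-separated manifest
#' @param kind library kind, \code{"dna"} or \code{"rna"}
#' @param outDir optional directory to save the library to
#' @return a [TemplateLibrary-class]
#' @export
buildLibraryFromManifest <- function(manifest, kind = "dna", outDir = NULL) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  templates <- list()
  seen <- character(0)
  for (i in seq_len(nrow(manifest))) {
    vi <- readVienna(manifest$dotbracket_path[i])
    db <- parseDotBracket(vi$ss)
    s <- readStructure(manifest$pdb_path[i])
    s <- completeAtoms(cleanAndStandardize(s))
    if (nResidues(s) != length(db)) {
      message("skipping ", manifest$id[i], ": length mismatch")
      next
    }
    sig <- paste(paste(residueCodes(s), collapse = ""), vi$ss)
    if (sig %in% seen) next               # exact duplicate structure
    seen <- c(seen, sig)
    cf <- corpusFilter(s, db)
    if (!cf$keep) next
    templates <- c(templates,
                   extractTemplates(s, db, sourceId = manifest$id[i],
                                    sourceKind = kind,
                                    resolution = manifest$resolution[i]))
  }
  lib <- templateLibrary(templates, kind)
  if (!is.null(outDir)) saveLibrary(lib, outDir)
  lib
}
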