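## All-atom structure handling: reading/writing PDB, residue
## standardization, ideal-geometry atom completion, base mutation and the
## 6-bead coarse-grained reduction.

.pkgEnv <- new.env(parent = emptyenv())

# atoms shared by all nucleotides (phosphate + sugar); O2' marks ribo
BACKBONE_SUGAR <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "C1'")
BEAD_ATOMS <- c("P", "C4'", "C2'", "C2", "C4", "C6")
STANDARD_DNA <- c("DA", "DC", "DG", "DT")
STANDARD_RNA <- c("A", "C", "G", "U")

# one-letter codes
BASE_LETTER <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                 A = "A", C = "C", G = "G", U = "U")
COMPLEMENT_DNA <- c(A = "T", C = "G", G = "C", T = "A")

# common modified / nonstandard nucleotides -> parent standard base
MODIFIED_BASE_MAP <- c(
  "5CM" = "DC", "5MC" = "C",  "OMC" = "C",  "5HC" = "DC", "C5"  = "DC",
  "DU"  = "DT", "BRU" = "DT", "UMS" = "DT", "5IU" = "DT", "5BU" = "DT",
  "8OG" = "DG", "6OG" = "DG", "7MG" = "G",  "2MG" = "G",  "M2G" = "G",
  "OMG" = "G",  "1MG" = "G",  "DI"  = "DG", "I"   = "G",
  "1MA" = "A",  "2MA" = "A",  "6MA" = "DA", "MA6" = "A",  "A2M" = "A",
  "PSU" = "U",  "5MU" = "U",  "H2U" = "U",  "4SU" = "U",  "2MU" = "U",
  "OMU" = "U",  "T"   = "DT", "THM" = "DT")

idealGeometry <- function() {
  if (is.null(.pkgEnv$ideal)) {
    path <- system.file("extdata", "bform_unit.tsv", package = "dnassembly")
    if (!nzchar(path))
      path <- file.path("inst", "extdata", "bform_unit.tsv")
    .pkgEnv$ideal <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .pkgEnv$ideal
}

#' Ideal residue geometry
#'
#' Coordinates of an idealized B-form nucleotide (helix axis along z,
#' 36 degree twist / 3.38 Angstrom rise repeating frame, Watson-Crick pair
#' dyad along x).  Used by the atom completion, base mutation and de novo
#' template construction machinery.
#'
#' @param resname one of DA, DC, DG, DT, A, C, G, U
#' @return numeric matrix (atoms x 3) with atom-name rownames
#' @export
idealResidue <- function(resname) {
  tab <- idealGeometry()
  sub <- tab[tab$resname == resname, ]
  if (!nrow(sub)) stop("no ideal geometry for residue: ", resname)
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$atom
  m
}

#' Construct a NucleicStructure from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{inscode}, \code{resname}, \code{elety}, \code{x}, \code{y},
#'   \code{z}; rows in file order.  The global residue ordinal
#'   \code{rindex} is (re)computed from changes of (chain, resno, inscode).
#' @return a [NucleicStructure-class]
#' @export
NucleicStructure <- function(atoms) {
  if (!nrow(atoms)) {
    atoms <- data.frame(chain = character(), resno = integer(),
                        inscode = character(), resname = character(),
                        elety = character(), x = numeric(), y = numeric(),
                        z = numeric(), rindex = integer())
    return(new("NucleicStructure", atoms = atoms))
  }
  key <- paste(atoms$chain, atoms$resno, atoms$inscode)
  atoms$rindex <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  rownames(atoms) <- NULL
  new("NucleicStructure", atoms = atoms)
}

#' @describeIn NucleicStructure-class number of residues
#' @param x a \code{NucleicStructure}
#' @export
setMethod("nResidues", "NucleicStructure", function(x) {
  if (!nrow(x@atoms)) 0L else max(x@atoms$rindex)
})

#' @describeIn NucleicStructure-class number of chains
#' @export
setMethod("nChains", "NucleicStructure", function(x) {
  length(unique(x@atoms$chain))
})

#' Per-residue summary table
#' @param s a [NucleicStructure-class]
#' @return data.frame with one row per residue: \code{rindex},
#'   \code{chain}, \code{resno}, \code{inscode}, \code{resname}
#' @export
residueTable <- function(s) {
  a <- s@atoms
  first <- !duplicated(a$rindex)
  data.frame(rindex = a$rindex[first], chain = a$chain[first],
             resno = a$resno[first], inscode = a$inscode[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}

#' @describeIn NucleicStructure-class one-letter residue codes
#' @export
setMethod("residueCodes", "NucleicStructure", function(x) {
  rn <- residueTable(x)$resname
  unname(ifelse(rn %in% names(BASE_LETTER), BASE_LETTER[rn], "N"))
})

setMethod("show", "NucleicStructure", function(object) {
  cat(sprintf("NucleicStructure: %d atom(s), %d residue(s), %d chain(s)\n",
              nrow(object@atoms), nResidues(object), nChains(object)))
  if (nResidues(object))
    cat(" ", paste(residueCodes(object), collapse = ""), "\n")
})

# coordinates of one residue as a named matrix
residueCoords <- function(s, rindex) {
  a <- s@atoms[s@atoms$rindex == rindex, ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$elety
  m
}

#' Read an all-atom structure from PDB text or file
#'
#' Parses ATOM/HETATM records (via bio3d) grouped by chain and residue
#' number; for multi-model (NMR) files only the first MODEL is used; for
#' alternate locations the highest-occupancy copy is kept (ties prefer
#' altloc 'A').
#'
#' @param pdb a file path or a character scalar/vector of PDB text
#' @param requireNucleic error when the file contains no nucleic residues
#'   (default TRUE)
#' @return a [NucleicStructure-class]
#' @export
readStructure <- function(pdb, requireNucleic = TRUE) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  # first MODEL only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed coordinate field at line %d", i))
  }
  if (!any(rec)) stop("no ATOM/HETATM records found")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pb$atom
  a$chain[is.na(a$chain)] <- "A"
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc: keep highest occupancy, tie -> 'A' (then first seen)
  if (any(a$alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety)
    pref <- order(-a$o, a$alt != "A" & a$alt != "", seq_len(nrow(a)))
    keep <- !duplicated(key[pref])
    a <- a[sort(pref[keep]), ]
  }
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      inscode = a$insert, resname = trimws(a$resid),
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  s <- NucleicStructure(atoms)
  known <- c(STANDARD_DNA, STANDARD_RNA, names(MODIFIED_BASE_MAP))
  if (requireNucleic && !any(atoms$resname %in% known))
    stop("no nucleic residues found")
  s
}

#' Write a structure as PDB text
#'
#' Standard fixed-width ATOM records, TER between chains, coordinates to
#' three decimals; \code{read(write(s))} reproduces residue names and
#' ordinals exactly and coordinates to 1e-3 Angstrom.
#'
#' @param s a [NucleicStructure-class]
#' @param path optional output file; when NULL the text is returned
#' @return the PDB text, invisibly when written to a file
#' @export
writeStructure <- function(s, path = NULL) {
  a <- s@atoms
  if (!nrow(a)) stop("cannot serialize an empty structure")
  if (nrow(a) + nChains(s) > 99999L) stop("too many atoms for PDB format")
  fmtName <- function(n) {
    if (nchar(n) >= 4L) substr(n, 1, 4) else sprintf(" %-3s", n)
  }
  element <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", a$elety)
  out <- character(0)
  serial <- 0L
  chains <- unique(a$chain)
  for (ch in chains) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, fmtName(a$elety[i]), a$resname[i], ch, a$resno[i],
        ifelse(nzchar(a$inscode[i]), a$inscode[i], " "),
        a$x[i], a$y[i], a$z[i], 1, 0, element[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    out <- c(out, sprintf("TER   %5d     %3s %1s%4d", serial,
                          a$resname[last], ch, a$resno[last]))
  }
  out <- c(out, "END")
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# guess the parent standard base of an unknown residue by ring-atom overlap
guessParentBase <- function(atomNames) {
  ribo <- "O2'" %in% atomNames
  cands <- if (ribo) STANDARD_RNA else STANDARD_DNA
  ov <- vapply(cands, function(rn) {
    base <- setdiff(rownames(idealResidue(rn)), c(BACKBONE_SUGAR, "O2'"))
    length(intersect(atomNames, base))
  }, 1L)
  cands[which.max(ov)]
}

#' Extract and standardize the nucleic part of a structure
#'
#' Removes non-nucleic residues (protein, water, ligands, ions), maps
#' nonstandard nucleotides to their parent standard base via a built-in
#' table (unknown nucleotide-like residues fall back to the standard base
#' with maximal base-atom name overlap), and drops atoms that do not belong
#' to the standard residue.  Residues still lacking one of the six
#' coarse-grain atoms can be listed afterwards with
#' [missingBeadResidues()].
#'
#' @param s a [NucleicStructure-class]
#' @return a standardized [NucleicStructure-class] (possibly empty)
#' @export
cleanAndStandardize <- function(s) {
  a <- s@atoms
  if (!nrow(a)) return(s)
  keepRows <- integer(0)
  newNames <- character(0)
  for (ri in unique(a$rindex)) {
    rows <- which(a$rindex == ri)
    rn <- a$resname[rows[1]]
    an <- a$elety[rows]
    std <- if (rn %in% c(STANDARD_DNA, STANDARD_RNA)) rn
           else if (rn %in% names(MODIFIED_BASE_MAP)) MODIFIED_BASE_MAP[[rn]]
           else if (all(c("C1'", "O4'") %in% an) &&
                    any(c("N9", "N1") %in% an)) guessParentBase(an)
           else NA_character_
    if (is.na(std)) next
    allowed <- c(rownames(idealResidue(std)), "OP3")
    rows <- rows[an %in% allowed]
    if (!length(rows)) next
    keepRows <- c(keepRows, rows)
    newNames <- c(newNames, rep(std, length(rows)))
  }
  a <- a[keepRows, ]
  if (nrow(a)) a$resname <- newNames
  out <- NucleicStructure(a[, c("chain", "resno", "inscode", "resname",
                                "elety", "x", "y", "z")])
  if (!nrow(out@atoms)) message("no nucleic residues retained")
  out
}

#' Residues lacking a coarse-grain bead atom
#' @param s a [NucleicStructure-class]
#' @return integer vector of rindex values of flagged residues
#' @export
missingBeadResidues <- function(s) {
  rt <- residueTable(s)
  bad <- vapply(rt$rindex, function(ri) {
    !all(BEAD_ATOMS %in% s@atoms$elety[s@atoms$rindex == ri])
  }, TRUE)
  rt$rindex[bad]
}

#' Rebuild missing atoms from ideal residue geometry
#'
#' For every residue, superposes the ideal residue geometry onto at least
#' three present reference atoms (Kabsch) and copies the missing atoms
#' through the fitted transform.  Residues with fewer than three usable
#' reference atoms are dropped (with a message).
#'
#' @param s a standardized [NucleicStructure-class]
#' @return a [NucleicStructure-class] with complete residues
#' @export
completeAtoms <- function(s) {
  a <- s@atoms
  if (!nrow(a)) return(s)
  keep <- list()
  for (ri in unique(a$rindex)) {
    rows <- which(a$rindex == ri)
    rn <- a$resname[rows[1]]
    if (!rn %in% c(STANDARD_DNA, STANDARD_RNA)) {
      message("dropping non-standard residue at rindex ", ri)
      next
    }
    ideal <- idealResidue(rn)
    present <- a$elety[rows]
    shared <- intersect(present, rownames(ideal))
    if (length(shared) < 3L) {
      message("dropping residue at rindex ", ri,
              ": fewer than 3 reference atoms")
      next
    }
    res <- a[rows, ]
    missing <- setdiff(rownames(ideal), present)
    if (length(missing)) {
      P <- ideal[shared, , drop = FALSE]
      Q <- as.matrix(res[match(shared, res$elety), c("x", "y", "z")])
      fit <- kabsch(P, Q)
      built <- applyTransform(ideal[missing, , drop = FALSE], fit)
      add <- res[rep(1L, length(missing)), ]
      add$elety <- missing
      add$x <- built[, 1]; add$y <- built[, 2]; add$z <- built[, 3]
      res <- rbind(res, add)
    }
    keep[[length(keep) + 1L]] <- res
  }
  if (!length(keep)) return(NucleicStructure(a[0, ]))
  a2 <- do.call(rbind, keep)
  NucleicStructure(a2[, c("chain", "resno", "inscode", "resname", "elety",
                          "x", "y", "z")])
}

# orthonormal base frame: origin at the glycosidic N, x toward C1',
# z along the ring normal from the common atoms C2, C4, C6
baseFrame <- function(coords) {
  glyN <- if ("N9" %in% rownames(coords)) "N9" else "N1"
  need <- c(glyN, "C1'", "C2", "C4", "C6")
  if (!all(need %in% rownames(coords)))
    stop("base frame needs atoms ", paste(need, collapse = ", "))
  o <- coords[glyN, ]
  ex <- coords["C1'", ] - o
  ex <- ex / sqrt(sum(ex^2))
  nrm <- crossProd(coords["C4", ] - coords["C2", ],
                   coords["C6", ] - coords["C2", ])
  ez <- nrm - sum(nrm * ex) * ex
  ez <- ez / sqrt(sum(ez^2))
  ey <- crossProd(ez, ex)
  list(origin = o, M = rbind(ex, ey, ez))
}

crossProd <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

normalizeBase <- function(base) {
  base <- toupper(base)
  full <- c(STANDARD_DNA, STANDARD_RNA)
  if (base %in% full) return(base)
  letter <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "U")
  if (base %in% names(letter)) return(letter[[base]])
  stop("unknown target base: ", base)
}

#' Mutate one residue to a different base
#'
#' Backbone and sugar atoms are untouched; the base atoms are replaced by
#' the ideal target-base geometry superposed on the base frame of the old
#' base, preserving the glycosidic attachment.  Converting a ribo residue
#' to a deoxy base removes the 2'-OH; U to T gains the C7 methyl from the
#' ideal geometry.
#'
#' @param s a [NucleicStructure-class]
#' @param chain chain identifier
#' @param ordinal residue number within the chain (\code{resno})
#' @param targetBase target base: DA/DC/DG/DT/A/C/G/U or a single letter
#' @return the mutated [NucleicStructure-class]
#' @export
mutateResidue <- function(s, chain, ordinal, targetBase) {
  rt <- residueTable(s)
  hit <- which(rt$chain == chain & rt$resno == ordinal)
  if (!length(hit))
    stop(sprintf("no residue %s:%d in structure", chain, ordinal))
  mutateResidueAt(s, rt$rindex[hit[1]], targetBase)
}

# rindex-addressed variant used internally by the assembler
mutateResidueAt <- function(s, rindex, targetBase) {
  target <- normalizeBase(targetBase)
  a <- s@atoms
  rows <- which(a$rindex == rindex)
  if (!length(rows)) stop("no residue with rindex ", rindex)
  coords <- residueCoords(s, rindex)
  fr <- baseFrame(coords)
  ideal <- idealResidue(target)
  idealFr <- baseFrame(ideal)
  baseAtoms <- setdiff(rownames(ideal), c(BACKBONE_SUGAR, "O2'"))
  local <- sweep(ideal[baseAtoms, , drop = FALSE], 2, idealFr$origin) %*%
    t(idealFr$M)
  placed <- local %*% fr$M + matrix(fr$origin, length(baseAtoms), 3,
                                    byrow = TRUE)
  isRibo <- target %in% STANDARD_RNA
  keepNames <- if (isRibo) c(BACKBONE_SUGAR, "O2'") else BACKBONE_SUGAR
  keepRows <- rows[a$elety[rows] %in% keepNames]
  res <- a[keepRows, ]
  add <- res[rep(1L, length(baseAtoms)), ]
  add$elety <- baseAtoms
  add$x <- placed[, 1]; add$y <- placed[, 2]; add$z <- placed[, 3]
  res <- rbind(res, add)
  res$resname <- target
  newA <- rbind(if (rindex > 1L) a[a$rindex < rindex, ] else NULL,
                res,
                if (rindex < max(a$rindex)) a[a$rindex > rindex, ] else NULL)
  NucleicStructure(newA[, c("chain", "resno", "inscode", "resname", "elety",
                            "x", "y", "z")])
}

#' @describeIn coarseGrain 6-bead reduction of a NucleicStructure
#' @export
setMethod("coarseGrain", "NucleicStructure", function(x) {
  rt <- residueTable(x)
  n <- nrow(rt)
  if (!n) stop("empty structure cannot be coarse-grained")
  coords <- matrix(NA_real_, 6L * n, 3L)
  for (k in seq_len(n)) {
    m <- residueCoords(x, rt$rindex[k])
    if (!all(BEAD_ATOMS %in% rownames(m)))
      stop(sprintf("residue %s:%d (%s) lacks a bead atom", rt$chain[k],
                   rt$resno[k], rt$resname[k]))
    coords[(k - 1L) * 6L + 1:6, ] <- m[BEAD_ATOMS, ]
  }
  new("CoarseModel", coords = coords, resname = rt$resname,
      chain = rt$chain)
})

#' @describeIn CoarseModel-class number of residues
#' @param x a \code{CoarseModel}
#' @export
setMethod("nResidues", "CoarseModel", function(x) length(x@resname))

setMethod("show", "CoarseModel", function(object) {
  cat(sprintf("CoarseModel: %d residue(s) x 6 beads\n", nResidues(object)))
})

# bead coordinate accessor: bead name for residue k
beadCoord <- function(cm, k, bead) {
  cm@coords[(k - 1L) * 6L + match(bead, BEAD_ATOMS), ]
}
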