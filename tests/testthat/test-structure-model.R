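# minimal hand-written PDB text for a single DA residue (bead atoms only)
miniDA <- function() {
  m <- idealResidue("DA")[c("P", "C4'", "C2'", "C2", "C4", "C6"), ]
  paste(c(sprintf(
    "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    1:6, sprintf(" %-3s", rownames(m)), "DA", "A", 1,
    m[, 1], m[, 2], m[, 3], 1, 0, substr(rownames(m), 1, 1)), "END"),
    collapse = "\n")
}

test_that("PDB reading maps records to chains, residues and atoms", {
  s <- readStructure(miniDA())
  expect_equal(nChains(s), 1)
  expect_equal(nResidues(s), 1)
  expect_equal(nrow(s@atoms), 6)
  expect_setequal(s@atoms$elety, c("P", "C4'", "C2'", "C2", "C4", "C6"))
})

test_that("only the first MODEL of a multi-model file is parsed", {
  one <- miniDA()
  body <- sub("\nEND$", "", one)
  shifted <- gsub("   0\\.", " 100.", body)   # crude coordinate change
  txt <- paste("MODEL        1", body, "ENDMDL", "MODEL        2",
               shifted, "ENDMDL", "END", sep = "\n")
  s <- readStructure(txt)
  expect_equal(nResidues(s), 1)
  s1 <- readStructure(one)
  expect_equal(s@atoms$x, s1@atoms$x, tolerance = 1e-6)
})

test_that("malformed coordinates and non-nucleic input are rejected", {
  line1 <- strsplit(miniDA(), "\n")[[1]][1]
  badline <- paste0(substr(line1, 1, 30), "abcdefgh", substr(line1, 39,
                                                             nchar(line1)))
  expect_error(readStructure(badline), "line 1")
  prot <- paste("ATOM      1  CA  ALA A   1      1.000   2.000   3.000",
                "END", sep = "\n")
  expect_error(readStructure(prot), "no nucleic")
})

test_that("write/read round trip preserves names, ordinals and coordinates", {
  fx <- testCorpus()
  for (f in fx[c(1, 5)]) {
    s <- f$structure
    s2 <- readStructure(writeStructure(s))
    expect_identical(residueTable(s2)$resname, residueTable(s)$resname)
    expect_identical(residueTable(s2)$resno, residueTable(s)$resno)
    expect_lt(max(abs(s2@atoms$x - s@atoms$x)), 1e-3)
    expect_lt(max(abs(s2@atoms$z - s@atoms$z)), 1e-3)
  }
  expect_error(writeStructure(NucleicStructure(data.frame())), "empty")
})

test_that("cleaning keeps nucleic residues and standardizes names", {
  fx <- testCorpus()[[1]]
  a <- fx$structure@atoms
  # graft a water and rename one residue to 5CM with a spurious atom
  wat <- a[1, ]; wat$resname <- "HOH"; wat$elety <- "O"; wat$resno <- 99L
  a2 <- a
  a2$resname[a2$rindex == 3] <- "5CM"
  extra <- a2[a2$rindex == 3, ][1, ]; extra$elety <- "CM5"
  s <- NucleicStructure(rbind(a2, extra, wat)[, c("chain", "resno",
    "inscode", "resname", "elety", "x", "y", "z")])
  cs <- cleanAndStandardize(s)
  rt <- residueTable(cs)
  expect_equal(nrow(rt), nResidues(fx$structure))   # water dropped
  expect_equal(rt$resname[3], "DC")                 # 5CM -> DC
  expect_false("CM5" %in% cs@atoms$elety)           # spurious atom dropped
  # all-protein input -> empty structure
  prot <- data.frame(chain = "A", resno = 1L, inscode = "",
                     resname = "ALA", elety = "CA", x = 0, y = 0, z = 0)
  expect_message(e <- cleanAndStandardize(NucleicStructure(prot)),
                 "no nucleic")
  expect_equal(nResidues(e), 0)
})

test_that("unknown nucleotide-like residues map by base-atom overlap", {
  fx <- testCorpus()[[1]]
  a <- fx$structure@atoms
  rt <- residueTable(fx$structure)
  g <- which(rt$resname == "DG")[1]
  a$resname[a$rindex == rt$rindex[g]] <- "XXG"
  s <- cleanAndStandardize(NucleicStructure(a[, c("chain", "resno",
    "inscode", "resname", "elety", "x", "y", "z")]))
  expect_equal(residueTable(s)$resname[g], "DG")
})

test_that("missing atoms are rebuilt on the ideal geometry", {
  fx <- testCorpus()[[1]]
  s <- fx$structure
  a <- s@atoms
  drop <- which(a$rindex == 4 & a$elety == "C2")
  ref <- as.numeric(a[drop, c("x", "y", "z")])
  s2 <- NucleicStructure(a[-drop, c("chain", "resno", "inscode", "resname",
                                    "elety", "x", "y", "z")])
  expect_equal(missingBeadResidues(s2), 4L)
  s3 <- completeAtoms(s2)
  expect_length(missingBeadResidues(s3), 0)
  rebuilt <- residueCoords(s3, 4)["C2", ]
  expect_lt(sqrt(sum((rebuilt - ref)^2)), 0.05)
  # complete residue passes through unchanged
  s4 <- completeAtoms(s)
  expect_equal(nrow(s4@atoms), nrow(s@atoms))
  expect_lt(max(abs(s4@atoms$x - s@atoms$x)), 1e-9)
  # a residue with only P cannot be fitted and is dropped
  lone <- a[a$rindex == 2 & a$elety == "P", ]
  a5 <- rbind(a[a$rindex == 1, ], lone)
  expect_message(
    s5 <- completeAtoms(NucleicStructure(a5[, c("chain", "resno", "inscode",
      "resname", "elety", "x", "y", "z")])), "fewer than 3")
  expect_equal(nResidues(s5), 1)
})

test_that("base mutation preserves the backbone and is near-invertible", {
  s <- testCorpus()[[1]]$structure
  rt <- residueTable(s)
  old <- rt$resname[3]
  target <- setdiff(c("DA", "DT"), old)[1]
  s2 <- mutateResidue(s, "A", 3, target)
  expect_equal(residueTable(s2)$resname[3], target)
  # backbone untouched
  m0 <- residueCoords(s, 3); m2 <- residueCoords(s2, 3)
  bb <- intersect(rownames(m0), c("P", "OP1", "OP2", "O5'", "C5'", "C4'",
                                  "O4'", "C3'", "O3'", "C2'", "C1'"))
  expect_lt(max(abs(m0[bb, ] - m2[bb, ])), 1e-12)
  # mutate back: base atoms return to within 0.2 A
  s3 <- mutateResidue(s2, "A", 3, old)
  m3 <- residueCoords(s3, 3)
  common <- intersect(rownames(m0), rownames(m3))
  expect_lt(max(sqrt(rowSums((m0[common, ] - m3[common, ])^2))), 0.2)
  # self-mutation is a near-identity
  s4 <- mutateResidue(s, "A", 3, old)
  m4 <- residueCoords(s4, 3)
  expect_lt(max(sqrt(rowSums((m0[common, ] - m4[common, ])^2))), 0.2)
  expect_error(mutateResidue(s, "A", 999, "DA"), "no residue")
  expect_error(mutateResidue(s, "A", 3, "DX"), "unknown target base")
})

test_that("RNA U converts to DT with the methyl gained and 2'-OH removed", {
  s <- testCorpus()[[1]]$structure
  # turn residue 3 into a ribo U (completeAtoms grafts the 2'-OH)
  s2 <- completeAtoms(dnassembly:::mutateResidueAt(s, 3, "U"))
  expect_true("O2'" %in% rownames(residueCoords(s2, 3)))
  s3 <- dnassembly:::mutateResidueAt(s2, 3, "DT")
  at <- rownames(residueCoords(s3, 3))
  expect_true("C7" %in% at)
  expect_false("O2'" %in% at)
  expect_equal(residueTable(s3)$resname[3], "DT")
})

test_that("coarse graining gives 6 beads per residue and is idempotent", {
  fx <- testCorpus()
  duplexSse <- decomposeSSE(parseDotBracket("(((((&)))))"),
                            "GCGCA&TGCGC")[[1]]
  tpl <- buildFallback(duplexSse)
  cm <- coarseGrain(tpl@fragment)
  expect_equal(nResidues(cm), 10)
  expect_equal(nrow(cm@coords), 60)
  # through a write/read round trip
  cm2 <- coarseGrain(readStructure(writeStructure(tpl@fragment)))
  expect_lt(max(abs(cm@coords - cm2@coords)), 2e-3)
  # missing bead atom errors with the residue named
  a <- tpl@fragment@atoms
  a <- a[!(a$rindex == 1 & a$elety == "P"), ]
  expect_error(coarseGrain(NucleicStructure(a[, c("chain", "resno",
    "inscode", "resname", "elety", "x", "y", "z")])), "lacks a bead atom")
})
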