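test_that("corpus filtering keeps only duplex-plus-loop structures", {
  dup <- decomposeSSE(parseDotBracket("((((((((((&))))))))))"),
                      "GCGCATATGC&GCATATGCGC")[[1]]
  s <- buildFallback(dup)@fragment
  cf <- corpusFilter(s, parseDotBracket("((((((((((&))))))))))"))
  expect_equal(cf$label, "Helix")
  expect_false(cf$keep)

  f <- testCorpus()[[1]]
  cf <- corpusFilter(f$structure, f$db)
  expect_equal(cf$label, "D")
  expect_true(cf$keep)

  # short and unstructured inputs are rejected
  open3 <- generateFixtures(fixtureSpec(list(
    list(id = "S3", ss = "...", seq = "ACG"))))[[1]]
  cf <- corpusFilter(open3$structure, open3$db)
  expect_equal(cf$label, "unStru")
  expect_false(cf$keep)
  tiny <- generateFixtures(fixtureSpec(list(
    list(id = "T3", ss = "(.)", seq = "GAC"))))[[1]]
  expect_false(corpusFilter(tiny$structure, tiny$db)$keep)
  expect_error(corpusFilter(open3$structure, f$db), "differ in length")
  # user annotation overrides
  expect_false(corpusFilter(f$structure, f$db, annotatedClass = "G")$keep)
})

test_that("template extraction mirrors the decomposition", {
  f <- testCorpus()[[5]]        # two-chain open/bulge/break architecture
  tpls <- extractTemplates(f$structure, f$db, sourceId = f$id)
  expect_length(tpls, 5)
  kinds <- vapply(tpls, function(t) t@sseKind, "")
  expect_equal(sort(kinds),
               sort(c("stem", "stem", "bulge", "open", "break")))
  # fragments carry as many residues as their local 2D says
  for (t in tpls)
    expect_equal(nResidues(t@fragment),
                 nchar(gsub("&", "", t@local2d, fixed = TRUE)))
  hp <- testCorpus()[[3]]       # hairpin-only molecule
  expect_length(extractTemplates(hp$structure, hp$db), 2)
})

test_that("topology keys are exact local dot-bracket identity", {
  expect_equal(topologyKey("((.&.))"), "((.&.))")
  expect_false(topologyKey("((...))") == topologyKey("((..))"))
  f <- testCorpus()[[5]]
  tpls <- extractTemplates(f$structure, f$db, sourceId = f$id)
  expect_equal(topologyKey(tpls[[1]]), tpls[[1]]@local2d)
})

test_that("the match score follows the 5 / 1.0 / 0.2 rule exactly", {
  # hairpin with a 4 bp stem (8 helix nt) and 3 loop nt
  sse <- decomposeSSE(parseDotBracket("((((...))))"), "GCGCAAAGCGC")[[2]]
  expect_equal(sse@local2d, "((...))")   # carries 2 boundary pairs
  # build a same-topology template with fully matching sequence
  tpl <- buildFallback(sse, sse@localSeq)
  sc <- scoreMatch(sse@local2d, sse@localSeq, tpl)
  expect_equal(sc$topologyPoints, 5)
  expect_equal(sc$loopMatches, 3)
  expect_equal(sc$helixMatches, 4)
  expect_equal(sc$total, 5 + 3 * 1.0 + 4 * 0.2)
  # zero sequence matches but same topology: exactly 5
  tpl2 <- buildFallback(sse, "CCCCCCC")
  expect_equal(scoreMatch(sse@local2d, "AAAAAAA", tpl2)$total, 5)
  # different topology, incomparable sequence: 0
  other <- decomposeSSE(parseDotBracket("((((....))))"), "GCGCAAAAGCGC")[[2]]
  tpl3 <- buildFallback(other, other@localSeq)
  expect_equal(scoreMatch(sse@local2d, sse@localSeq, tpl3)$total, 0)
  # monotonicity: one extra matching loop nucleotide adds exactly 1.0,
  # one extra matching helix nucleotide exactly 0.2
  sA <- scoreMatch(sse@local2d, "AAAAAAA", tpl2)$total
  sB <- scoreMatch(sse@local2d, "AAAAAAA", buildFallback(sse, "CCACCCC"))$total
  expect_equal(sB - sA, 1.0)
  sC <- scoreMatch(sse@local2d, "AAAAAAA", buildFallback(sse, "ACCCCCC"))$total
  expect_equal(sC - sA, 0.2)
})

test_that("library search honours exclusions, fallbacks and tie-breaks", {
  lib <- testLibrary()
  f <- testCorpus()[[1]]
  sses <- decomposeSSE(f$db, f$seq)
  hp <- Filter(function(s) s@kind == "hairpin", sses)[[1]]
  # own source excluded: a same-topology template from elsewhere wins
  res <- searchTemplate(hp, lib, exclude = f$id)
  expect_true(res$perfect)
  expect_false(res$template@sourceId == f$id)
  expect_equal(res$template@local2d, hp@local2d)
  # nothing excluded: own (perfect-scoring) template wins
  res2 <- searchTemplate(hp, lib)
  expect_equal(res2$score, 5 + sum(strsplit(gsub("&", "", hp@local2d),
    "")[[1]] == ".") + 0.2 * sum(strsplit(gsub("&", "", hp@local2d),
    "")[[1]] != "."))
  # unknown topology falls back to a de novo template
  novel <- decomposeSSE(parseDotBracket("((.........))"),
                        "GCAAAAAAAAAGC")[[2]]
  res3 <- searchTemplate(novel, lib)
  expect_false(res3$perfect)
  expect_equal(res3$template@sourceKind, "denovo")
})

test_that("RNA fallback converts U to T before returning the fragment", {
  # an RNA-only topology: ribo copy of a hairpin absent from the DNA lib
  ss <- "(((.......)))"
  mol <- generateFixtures(fixtureSpec(list(
    list(id = "RNA1", ss = ss, seq = "GCGUUUCCCGCGC"))))[[1]]
  s <- mol$structure
  for (k in seq_len(nResidues(s))) {
    code <- residueCodes(s)[k]
    s <- dnassembly:::mutateResidueAt(s, k, ifelse(code == "T", "U", code))
  }
  s <- completeAtoms(s)    # grafts the 2'-OH
  rnaLib <- templateLibrary(extractTemplates(s, mol$db, sourceId = "RNA1",
                                             sourceKind = "rna"), "rna")
  lib <- testLibrary()
  query <- decomposeSSE(parseDotBracket(ss), "GCGAAAAAAAGCG")
  loops <- Filter(function(x) x@kind == "hairpin", query)
  res <- searchTemplate(loops[[1]], lib, rnaLib)
  expect_false(res$perfect)
  expect_equal(res$template@sourceKind, "rna")
  codes <- residueCodes(res$template@fragment)
  expect_false("U" %in% codes)
  expect_false("O2'" %in% res$template@fragment@atoms$elety)
})

test_that("de novo fragments have sane covalent and pairing geometry", {
  # 4 bp stem: 8 residues, paired C1'-C1' near 10.4 A
  stem <- decomposeSSE(parseDotBracket("((((....))))"), "GCGCAAAAGCGC")[[1]]
  expect_equal(stem@kind, "stem")
  frag <- buildFallback(stem)@fragment
  expect_equal(nResidues(frag), 8)
  for (k in 1:4) {
    c1a <- residueCoords(frag, k)["C1'", ]
    c1b <- residueCoords(frag, 9 - k)["C1'", ]
    expect_equal(sqrt(sum((c1a - c1b)^2)), 10.4, tolerance = 0.5 / 10.4)
  }
  # hairpin closure gap
  hp <- decomposeSSE(parseDotBracket("((....))"), "GCAAAAGC")[[2]]
  gaps <- dnassembly:::junctionGaps(buildFallback(hp)@fragment)
  expect_lt(max(gaps), 2.5)
  # a 0-nt bulge side reduces to pure helix stacking; the fragment's two
  # stubs sit coaxially, so every true backbone link is near-ideal (the jump
  # between local positions 5 and 6 crosses the excised child hairpin and
  # is not a bond)
  sses <- decomposeSSE(parseDotBracket("((.((...))))"), "GCAGCAAAGCGC")
  bulge <- Filter(function(x) x@kind == "bulge", sses)[[1]]
  bfrag <- buildFallback(bulge)@fragment
  g <- dnassembly:::junctionGaps(bfrag)
  expect_lt(max(g[-5]), 2.5)
  expect_lt(abs(g[7] - 1.6), 0.1)    # the 0-nt side stacks seamlessly
})

test_that("a library survives a save/load round trip", {
  lib <- testLibrary()
  dir <- file.path(tempdir(), "libtest")
  saveLibrary(lib, dir)
  lib2 <- loadLibrary(dir)
  expect_equal(length(lib2@templates), length(lib@templates))
  expect_setequal(names(lib2@index), names(lib@index))
  # a reloaded library answers searches identically
  f <- testCorpus()[[1]]
  hp <- Filter(function(s) s@kind == "hairpin",
               decomposeSSE(f$db, f$seq))[[1]]
  r1 <- searchTemplate(hp, lib, exclude = f$id)
  r2 <- searchTemplate(hp, lib2, exclude = f$id)
  expect_equal(r1$template@sourceId, r2$template@sourceId)
  expect_equal(r1$score, r2$score)
  unlink(dir, recursive = TRUE)
})

test_that("leave-one-out search is complete over the corpus", {
  lib <- testLibrary()
  for (f in testCorpus()) {
    for (sse in decomposeSSE(f$db, f$seq)) {
      res <- searchTemplate(sse, lib, exclude = f$id)
      # every topology occurs in at least two fixtures, so a same-topology
      # template must be found without de novo fallback
      expect_true(res$perfect)
      expect_false(res$template@sourceId == f$id)
    }
  }
})
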