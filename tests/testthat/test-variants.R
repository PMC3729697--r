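test_that("tokens parse into the documented classes", {
  v <- parseVariant(c("8616T", "195@", "16292", "309.1C", "249d", "16147G"))
  expect_equal(v$var_class,
               c("transversion", "back_mutation", "transition",
                 "insertion", "deletion", "transversion"))
  expect_equal(v$position[1:3], c(8616L, 195L, 16292L))
  expect_equal(v$derived_base[1], "T")
  expect_true(v$back_mutation[2])
  expect_equal(v$insert_index[4], 1L)
  # case-insensitive input canonicalises to upper case
  expect_equal(parseVariant("8616t")$token, "8616T")
})

test_that("malformed tokens fail with the offending token named", {
  for (bad in c("0A", "16570", "12X", "309.1", "309.0C", "", "abc",
                "249d@", "12.1C@")) {
    expect_error(parseVariant(bad), "malformed")
  }
  expect_error(parseVariant("0A"), "0A")
})

test_that("parse-render round trip is the identity on the grammar", {
  set.seed(11)
  for (i in 1:200) {
    pos <- sample(16569, 1)
    kind <- sample(c("plain", "base", "back", "baseback", "del", "ins"), 1)
    tok <- switch(kind,
      plain = as.character(pos),
      base = paste0(pos, sample(c("A", "C", "G", "T"), 1)),
      back = paste0(pos, "@"),
      baseback = paste0(pos, sample(c("A", "C", "G", "T"), 1), "@"),
      del = paste0(pos, "d"),
      ins = paste0(pos, ".", sample(3, 1), sample(c("A", "C", "G", "T"), 1)))
    v <- parseVariant(tok)
    expect_identical(renderVariant(v), tok)
    expect_identical(parseVariant(renderVariant(v)), v)
  }
})

test_that("sequence comparison matches a brute-force column oracle", {
  ref20 <- "ACGTACGTACGTACGTACGT"
  expect_length(variantTokens(
    profileFromSequence(ref20, ref20, reference = "toy")), 0)

  # single A->G transition at column 5
  s <- sub("^(.{4})A", "\\1G", ref20)
  p <- profileFromSequence(s, ref20, reference = "toy")
  expect_identical(variantTokens(p), "5")
  expect_identical(variantTokens(p), oracleDiffTokens(s, ref20))

  # single A->C transversion
  s2 <- sub("^(.{4})A", "\\1C", ref20)
  p2 <- profileFromSequence(s2, ref20, reference = "toy")
  expect_identical(variantTokens(p2), "5C")
  v <- parseVariant(variantTokens(p2))
  expect_equal(v$var_class, "transversion")
  expect_equal(v$derived_base, "C")

  set.seed(21)
  for (i in 1:40) {
    pr <- randomSeqPair(len = sample(20:60, 1), nDiff = sample(0:6, 1))
    expect_setequal(
      variantTokens(profileFromSequence(pr$seq, pr$ref, reference = "toy")),
      oracleDiffTokens(pr$seq, pr$ref))
  }
})

test_that("gapped alignments yield indel tokens; bad input is rejected", {
  p <- profileFromSequence("AC-TA", "ACGTA", reference = "toy")
  expect_identical(variantTokens(p), "3d")
  p2 <- profileFromSequence("ACGTTA", "ACG-TA", reference = "toy")
  expect_identical(variantTokens(p2), "3.1T")
  # gap placement in a homopolymer tract is left-aligned, hence stable
  pa <- profileFromSequence("AAC-CCT", "AACCCCT", reference = "toy")
  pb <- profileFromSequence("AACCC-T", "AACCCCT", reference = "toy")
  expect_identical(variantTokens(pa), variantTokens(pb))

  expect_error(profileFromSequence("ACG", "ACGT", reference = "toy"),
               "length")
  expect_error(profileFromSequence("ACNT", "ACGT", reference = "toy"),
               "ambiguity|non-IUPAC")
})

test_that("mask removes exactly the listed identities", {
  p <- variantProfile("s", c("16519", "10034"))
  expect_identical(variantTokens(applyMask(p)), "10034")
  expect_identical(sampleID(applyMask(p)), "s")
  # input unchanged
  expect_identical(variantTokens(p), c("10034", "16519"))

  empty <- variantProfile("e", character())
  expect_length(variantTokens(applyMask(empty)), 0)

  clean <- variantProfile("c", c("100", "200", "300"))
  expect_length(variantTokens(applyMask(clean)), 3)

  # base-specific mask entries only hit that derived state
  expect_identical(applyMask(c("16182C", "16182G", "16183C"),
                             defaultSiteMask()),
                   "16182G")
  # bare-position mask entries hit every event at the position
  expect_length(applyMask(c("16519", "16519A"), defaultSiteMask()), 0)
})

test_that("profile distance is the masked symmetric difference and a metric", {
  a <- variantProfile("a", c("10034", "16129"))
  b <- variantProfile("b", "16129")
  expect_equal(profileDistance(a, a), 0)
  expect_equal(profileDistance(a, b), 1)
  expect_error(profileDistance(a, variantProfile("c", "16129",
                                                 reference = "RSRS")),
               "reference")

  symdiff <- function(x, y) length(setdiff(x, y)) + length(setdiff(y, x))
  set.seed(31)
  for (i in 1:50) {
    ts <- randomTokenSets(3)
    ps <- profilesFromTokenSets(ts, c("x", "y", "z"))
    m <- emptySiteMask()
    dxy <- profileDistance(ps[[1]], ps[[2]], m)
    dxz <- profileDistance(ps[[1]], ps[[3]], m)
    dyz <- profileDistance(ps[[2]], ps[[3]], m)
    expect_equal(dxy, symdiff(ts[[1]], ts[[2]]))
    expect_equal(dxy, profileDistance(ps[[2]], ps[[1]], m))
    expect_equal(dxy == 0, setequal(ts[[1]], ts[[2]]))
    expect_lte(dxz, dxy + dyz)
  }
})

test_that("profiles reject duplicates at one position and enforce regions", {
  expect_error(variantProfile("s", c("152", "152A")), "duplicated")
  expect_error(variantProfile("s", "12345", region = "HVS-I"), "region")
  expect_silent(variantProfile("s", c("16129", "73"),
                               region = "control_region"))
  expect_error(variantProfile("s", "8000", region = "control_region"),
               "region")
})

test_that("profile tables round-trip through the TSV format", {
  ps <- list(variantProfile("s1", c("16129", "8616T")),
             variantProfile("s2", character()))
  f <- tempfile(fileext = ".tsv")
  writeProfiles(ps, f)
  back <- readProfiles(f)
  expect_equal(vapply(back, sampleID, ""), c("s1", "s2"))
  expect_identical(variantTokens(back[[1]]), c("8616T", "16129"))
  expect_length(variantTokens(back[[2]]), 0)
})

test_that("FASTA records are called against a named reference", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">ref", "ACGTACGT", ">s1", "ACGTACGT", ">s2", "ACTTACGT"), f)
  ps <- profilesFromFasta(f, refName = "ref")
  expect_equal(vapply(ps, sampleID, ""), c("s1", "s2"))
  expect_length(variantTokens(ps[[1]]), 0)
  expect_identical(variantTokens(ps[[2]]), "3T")
})
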