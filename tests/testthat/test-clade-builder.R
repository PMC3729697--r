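test_that("identical haplotypes collapse to one cluster under the root", {
  ps <- profilesFromTokenSets(rep(list(c("100", "200")), 3),
                              c("a", "b", "c"))
  tr <- buildCladeTree(ps)
  expect_equal(nodeCount(tr), 2)
  expect_setequal(nodeSamples(tr)[[2]], c("a", "b", "c"))
  expect_setequal(edgeMutations(tr)[[2]], c("100", "200"))
  expect_equal(parsimonyScore(tr), 2)
})

test_that("a forced split shares the common edge", {
  ps <- profilesFromTokenSets(list(c("100", "200", "300"),
                                   c("100", "200", "400")),
                              c("s1", "s2"))
  tr <- buildCladeTree(ps)
  expect_equal(parsimonyScore(tr), 4)
  shared <- which(vapply(edgeMutations(tr), function(t)
    setequal(t, c("100", "200")), logical(1)))
  expect_length(shared, 1)
  sub <- detectSubclades(tr, minTips = 2)
  expect_equal(nrow(sub), 1)
  expect_equal(sub$nTips, 2)
  expect_setequal(strsplit(sub$mutations, ",")[[1]], c("100", "200"))
})

test_that("root-to-tip replay reproduces every masked input profile", {
  set.seed(51)
  for (i in 1:200) {
    ts <- randomTokenSets(sample(2:8, 1))
    names(ts) <- paste0("s", seq_along(ts))
    tr <- buildCladeTree(profilesFromTokenSets(ts), mask = emptySiteMask())
    rep_ <- replayProfiles(tr)
    for (nm in names(ts)) expect_setequal(rep_[[nm]], ts[[nm]])
  }
})

test_that("greedy construction attains the exhaustive parsimony optimum", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (i in 1:12) {
    ts <- perfectPhylogenyTokens(nTips = sample(4:6, 1),
                                 nSites = sample(5:10, 1))
    tr <- buildCladeTree(profilesFromTokenSets(ts), mask = emptySiteMask())
    nVariants <- length(unique(unlist(ts)))
    expect_equal(parsimonyScore(tr), nVariants)   # homoplasy-free closed form
    expect_equal(parsimonyScore(tr), exhaustiveParsimony(ts))
    expect_equal(nrow(homoplasyScan(tr)), 0)
  }
})

test_that("duplicating a haplotype changes neither topology nor score", {
  set.seed(71)
  ts <- perfectPhylogenyTokens(5, 8)
  ps <- profilesFromTokenSets(ts)
  tr1 <- buildCladeTree(ps, mask = emptySiteMask())
  dup <- c(ps, list(variantProfile("dup1", ts[[2]])))
  tr2 <- buildCladeTree(dup, mask = emptySiteMask())
  expect_equal(parsimonyScore(tr2), parsimonyScore(tr1))
  expect_equal(nodeCount(tr2), nodeCount(tr1))
  expect_equal(tr2@parent, tr1@parent)
  # the duplicate sits with its twin
  host <- which(vapply(nodeSamples(tr2), function(s) "dup1" %in% s,
                       logical(1)))
  expect_true("t2" %in% nodeSamples(tr2)[[host]])
})

test_that("input validation catches duplicates and mixed references", {
  ps <- profilesFromTokenSets(list("100", "200"), c("a", "a"))
  expect_error(buildCladeTree(ps), "duplicate sample ids")
  ps2 <- list(variantProfile("a", "100"),
              variantProfile("b", "100", reference = "RSRS"))
  expect_error(buildCladeTree(ps2), "references")
  expect_error(buildCladeTree(list(
    variantProfile("a", c("100", "195@"))), mask = emptySiteMask()),
    "back-mutation")
})

test_that("star trees yield no subclades", {
  ps <- profilesFromTokenSets(list("101", "202", "303"), c("a", "b", "c"))
  tr <- buildCladeTree(ps, mask = emptySiteMask())
  expect_equal(nrow(detectSubclades(tr, 2)), 0)
})

test_that("subclades recovered from a simulated genealogy match the truth", {
  sim <- simulateClade(nTips = 12, tmrcaYears = 15000, seed = 81,
                       hotspotMultiplier = 1)
  tr <- buildCladeTree(sim@profiles, mask = emptySiteMask())
  if (nrow(homoplasyScan(tr)) == 0) {
    truePart <- ape::prop.part(sim@truth$tree)
    labs <- sim@truth$tree$tip.label
    trueClades <- lapply(truePart, function(ix) sort(labs[ix]))
    below <- detectSubclades(tr, minTips = 2)
    for (nd in below$node) {
      nodes <- mitochron:::.subtreeNodes(tr, nd)
      samp <- sort(unlist(nodeSamples(tr)[nodes]))
      expect_true(any(vapply(trueClades, identical, logical(1), y = samp)))
    }
  } else succeed("recurrent hits present; partition check not applicable")
})

test_that("homoplasy scan reports planted recurrent positions", {
  clean <- manualTree(parent = c(NA, 1, 2, 2),
                      edgeTokens = list(character(), "100", "200", "300"),
                      samples = list(character(), character(), "a", "b"))
  expect_equal(nrow(homoplasyScan(clean)), 0)

  # position 185 on three separate edges
  tr <- manualTree(parent = c(NA, 1, 1, 1, 2),
                   edgeTokens = list(character(), c("185", "300"), "185",
                                     "410", "185@"),
                   samples = list(character(), character(), "a", "b", "c"))
  h <- homoplasyScan(tr)
  expect_equal(h$occurrences[h$position == 185], 3)

  set.seed(91)
  for (i in 1:20) {
    nEdge <- sample(4:7, 1)
    planted <- sample(2:(nEdge - 1), 1)
    toks <- c(rep(list("555"), planted),
              lapply(seq_len(nEdge - planted), function(j)
                as.character(600 + j)))
    toks <- toks[sample(nEdge)]
    tr <- manualTree(parent = c(NA, rep(1L, nEdge)),
                     edgeTokens = c(list(character()), toks),
                     samples = c(list(character()),
                                 as.list(paste0("s", seq_len(nEdge)))))
    h <- homoplasyScan(tr)
    expect_equal(h$occurrences[h$position == 555], planted)
    expect_equal(nrow(h), 1)
  }
})

test_that("newick export carries samples and mutation annotations", {
  ps <- profilesFromTokenSets(list(c("100", "200", "300"),
                                   c("100", "200", "400")),
                              c("s1", "s2"))
  tr <- buildCladeTree(ps)
  nwk <- writeNewick(tr)
  expect_match(nwk, "s1:0")
  expect_match(nwk, "mutations=100\\|200")
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  # the backbone (comments stripped) is readable by standard tools
  plain <- gsub("\\[[^]]*\\]", "", readLines(f))
  expect_s3_class(ape::read.tree(text = plain), "phylo")
  et <- edgeTable(tr)
  expect_equal(nrow(et), nodeCount(tr) - 1)
})
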