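# Shared fixtures and independent oracles (deliberately written without
# using the package's own internals).

# Brute-force column-by-column variant caller on ungapped alignments.
oracleDiffTokens <- function(seq, ref) {
  s <- strsplit(toupper(seq), "")[[1]]
  r <- strsplit(toupper(ref), "")[[1]]
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  out <- character()
  for (i in seq_along(r)) {
    if (s[i] == r[i]) next
    out <- c(out, if (identical(partner[[r[i]]], s[i])) as.character(i)
             else paste0(i, s[i]))
  }
  out
}

# Random ungapped sequence pair over ACGT.
randomSeqPair <- function(len, nDiff) {
  bases <- c("A", "C", "G", "T")
  r <- sample(bases, len, replace = TRUE)
  s <- r
  at <- sample(len, nDiff)
  for (i in at) s[i] <- sample(setdiff(bases, s[i]), 1)
  list(seq = paste(s, collapse = ""), ref = paste(r, collapse = ""))
}

# Random transition-token profiles over a small site pool.
randomTokenSets <- function(nProfiles, nSites = 30, maxTokens = 8) {
  lapply(seq_len(nProfiles), function(i)
    as.character(sort(sample(100 + seq_len(nSites) * 3,
                             sample(0:maxTokens, 1)))))
}

# Homoplasy-free haplotypes: a random rooted binary tree over the tips,
# each site mutating exactly once on a random edge.
perfectPhylogenyTokens <- function(nTips, nSites) {
  # random nested partition via sequential attachment
  parent <- c(NA, 1L)                     # node 1 = root, node 2 = first child
  for (k in seq_len(nTips - 1L)) {
    cand <- seq_along(parent)[-1L]
    parent <- c(parent, cand[sample.int(length(cand), 1L)])
  }
  nNode <- length(parent)
  tipNodes <- sample(seq(2L, nNode), nTips)
  siteEdge <- sample(seq(2L, nNode), nSites, replace = TRUE)
  toks <- lapply(tipNodes, function(tip) {
    path <- integer()
    cur <- tip
    while (!is.na(parent[cur])) { path <- c(path, cur); cur <- parent[cur] }
    as.character(sort(1000L + which(siteEdge %in% path)))
  })
  names(toks) <- paste0("t", seq_len(nTips))
  toks
}

# Exhaustive minimum parsimony over all topologies, via Fitch parsimony
# on every unrooted tree with an all-ancestral pseudo-tip as the root.
exhaustiveParsimony <- function(tokenSets) {
  sites <- sort(unique(unlist(tokenSets)))
  mat <- t(vapply(tokenSets, function(t)
    as.integer(sites %in% t), integer(length(sites))))
  mat <- rbind(mat, ROOT = 0L)
  rownames(mat) <- c(paste0("x", seq_along(tokenSets)), "ROOT")
  dat <- phangorn::phyDat(mat, type = "USER", levels = c(0L, 1L))
  trees <- phangorn::allTrees(nrow(mat), rooted = FALSE,
                              tip.label = rownames(mat))
  min(vapply(trees, function(tr) phangorn::parsimony(tr, dat), numeric(1)))
}

profilesFromTokenSets <- function(tokenSets, ids = NULL) {
  if (is.null(ids)) ids <- names(tokenSets)
  if (is.null(ids)) ids <- paste0("s", seq_along(tokenSets))
  mapply(function(t, id) variantProfile(id, t), tokenSets, ids,
         SIMPLIFY = FALSE)
}

# Hand-built phylogeny with explicit edge mutations (for planted-truth
# homoplasy and sigma tests).
manualTree <- function(parent, edgeTokens, samples, reference = "rCRS") {
  n <- length(parent)
  new("CladePhylogeny", parent = as.integer(parent),
      edgeTokens = edgeTokens, samples = samples,
      labels = rep(NA_character_, n), reference = reference)
}

# Shared clock instance (calibration is deterministic; build once).
sharedClock <- local({
  clk <- NULL
  function() {
    if (is.null(clk)) clk <<- correctedClock()
    clk
  }
})
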