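# Coalescent simulation of mitogenome clades with known node times.

.BASES <- c("A", "C", "G", "T")

#' Simulate a mitogenome clade with known genealogy
#'
#' Draws a Kingman coalescent genealogy (or uses a supplied one), rescales
#' it to a known TMRCA, and drops Poisson mutations on every branch.  The
#' expected substitution count of a branch spanning ages `t1 > t2` is
#' taken from the corrected clock (`D(t1) - D(t2)` with `D` the inverse
#' clock mapping), so the simulated mutation density is exactly the one
#' the dating machinery assumes; a constant `ratePerYear` can be supplied
#' instead.  Mutated sites are drawn from a hotspot-weighted distribution
#' over the 16,569-site molecule; each hit is a transition with
#' probability `1 - tvFraction`, otherwise a transversion to a random
#' non-transition base.  A second hit at an already-derived site either
#' restores the ancestral base (a reversion, rendered `"<pos>@"` in the
#' truth records — for transitions this happens with probability 1/2 per
#' the two-state symmetry) or moves to another derived state.
#'
#' Everything is reproducible from `seed`; a fixed seed gives
#' byte-identical output.
#'
#' @param nTips number of sampled lineages (>= 1).
#' @param tmrcaYears known root age in years (the genealogy is rescaled to
#'   it).  Mutually exclusive with `Ne`.
#' @param Ne coalescent effective-size parameter in years (branch lengths
#'   of the unit coalescent are multiplied by it); the realised TMRCA then
#'   varies between replicates.
#' @param seed mandatory RNG seed.
#' @param clock a [ClockModel-class]; default [correctedClock()].
#' @param ratePerYear optional constant substitution rate per genome per
#'   year, overriding the clock (0 gives mutation-free tips).
#' @param tree optional `phylo` genealogy with branch lengths in years
#'   (overrides `nTips`/`tmrcaYears`/`Ne`).
#' @param hotspotPositions sites with elevated mutability.
#' @param hotspotMultiplier rate multiplier at those sites (default 10).
#' @param tvFraction fraction of hits that are transversions.
#' @param reference name recorded on the emitted profiles.
#' @param emitSequences when `FALSE`, skip building the per-tip
#'   [VariantProfile-class] objects and the FASTA set (the truth records
#'   are complete either way); useful for large replicate studies that
#'   only need mutation counts.
#' @return a [CladeSimulation-class]: truth records (genealogy, node ages,
#'   per-edge planted mutation tokens, root sequence), one
#'   [VariantProfile-class] per tip, and a `DNAStringSet` holding the root
#'   reference plus all tip sequences.
#' @examples
#' sim <- simulateClade(nTips = 5, tmrcaYears = 12000, seed = 42)
#' sim
#' @export
simulateClade <- function(nTips = 50L, tmrcaYears = NULL, Ne = NULL,
                          seed, clock = NULL, ratePerYear = NULL,
                          tree = NULL,
                          hotspotPositions = defaultHotspotSites(),
                          hotspotMultiplier = 10, tvFraction = 0.05,
                          reference = "simref", emitSequences = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (!is.null(tmrcaYears) && !is.null(Ne))
    stop("inconsistent configuration: give either tmrcaYears or Ne, not both")
  set.seed(seed)
  L <- .MT_LENGTH

  if (is.null(tree)) {
    if (nTips < 1L) stop("nTips must be >= 1")
    if (nTips == 1L) {
      tree <- structure(list(
        edge = matrix(c(2L, 1L), 1L, 2L),
        edge.length = if (!is.null(tmrcaYears)) tmrcaYears else
          if (!is.null(Ne)) Ne else 12000,
        tip.label = "t1", Nnode = 1L), class = "phylo")
    } else {
      tree <- ape::rcoal(nTips)
      depth <- max(ape::node.depth.edgelength(tree))
      scale <- if (!is.null(tmrcaYears)) tmrcaYears / depth
      else if (!is.null(Ne)) Ne
      else 12000 / depth
      tree$edge.length <- tree$edge.length * scale
    }
  }
  ntip <- length(tree$tip.label)
  dep <- ape::node.depth.edgelength(tree)
  rootAge <- max(dep)
  ages <- pmax(rootAge - dep, 0)

  if (is.null(ratePerYear) && is.null(clock)) clock <- correctedClock()
  expSubs <- function(hi, lo) {
    if (!is.null(ratePerYear)) return(ratePerYear * (hi - lo))
    clock@inverse(hi / 1000) - clock@inverse(lo / 1000)
  }

  siteW <- rep(1, L)
  siteW[hotspotPositions] <- hotspotMultiplier
  siteW <- siteW / sum(siteW)

  rootSeq <- sample(.BASES, L, replace = TRUE)
  nNode <- ntip + tree$Nnode
  seqs <- vector("list", nNode)
  rootNode <- ntip + 1L
  seqs[[rootNode]] <- rootSeq
  edgeTokens <- vector("list", nNode)

  ord <- order(dep[tree$edge[, 1L]])      # parents before children
  for (e in ord) {
    pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    lam <- expSubs(ages[pa], ages[ch])
    nmut <- rpois(1L, lam)
    s <- seqs[[pa]]
    if (nmut > 0L) {
      sites <- sample.int(L, nmut, replace = TRUE, prob = siteW)
      for (pos in sites) {
        cur <- s[pos]
        if (runif(1L) > tvFraction) s[pos] <- .TRANSITION_PARTNER[[cur]]
        else s[pos] <- sample(setdiff(.BASES, c(cur, .TRANSITION_PARTNER[[cur]])), 1L)
      }
    }
    seqs[[ch]] <- s
    # edge truth: net state changes vs the parent, tokens relative to root
    chg <- which(s != seqs[[pa]])
    edgeTokens[[ch]] <- vapply(chg, function(pos) {
      b <- s[pos]
      if (b == rootSeq[pos]) paste0(pos, "@")
      else if (.TRANSITION_PARTNER[[rootSeq[pos]]] == b) as.character(pos)
      else paste0(pos, b)
    }, character(1L))
  }

  if (emitSequences) {
    profiles <- lapply(seq_len(ntip), function(i)
      profileFromSequence(paste(seqs[[i]], collapse = ""),
                          paste(rootSeq, collapse = ""),
                          sampleID = tree$tip.label[i],
                          reference = reference))
    fasta <- Biostrings::DNAStringSet(c(
      setNames(paste(rootSeq, collapse = ""), reference),
      setNames(vapply(seq_len(ntip), function(i)
        paste(seqs[[i]], collapse = ""), character(1L)), tree$tip.label)))
  } else {
    profiles <- list()
    fasta <- NULL
  }

  new("CladeSimulation",
      truth = list(tree = tree, tmrcaYears = rootAge, nodeAgesYears = ages,
                   edgeTokens = edgeTokens, rootSequence =
                     paste(rootSeq, collapse = "")),
      profiles = profiles, fasta = fasta)
}

#' The known genealogy of a simulation as a clade phylogeny
#'
#' Converts a simulation's truth records (the scaled coalescent tree with
#' its planted per-edge mutation tokens) into a [CladePhylogeny-class],
#' with each tip's label attached as a sample at the corresponding node.
#' This is the tree the estimators would see under a perfect
#' reconstruction, and the natural input for parameter-recovery studies
#' on the *known* genealogy (as opposed to the rebuilt parsimony tree).
#'
#' @param sim a [CladeSimulation-class].
#' @return a [CladePhylogeny-class].
#' @export
truthPhylogeny <- function(sim) {
  tr <- sim@truth$tree
  ntip <- length(tr$tip.label)
  rootPh <- ntip + 1L
  parentOf <- integer(ntip + tr$Nnode)
  childrenOf <- split(tr$edge[, 2L], tr$edge[, 1L])
  # breadth-first numbering so parents precede children
  order <- rootPh
  queue <- rootPh
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- childrenOf[[as.character(v)]]
    order <- c(order, kids)
    queue <- c(queue, kids[kids > ntip])
  }
  newId <- setNames(seq_along(order), order)
  parent <- rep(NA_integer_, length(order))
  for (e in seq_len(nrow(tr$edge)))
    parent[newId[[as.character(tr$edge[e, 2L])]]] <-
      newId[[as.character(tr$edge[e, 1L])]]
  edgeTokens <- rep(list(character()), length(order))
  samples <- rep(list(character()), length(order))
  for (v in order) {
    i <- newId[[as.character(v)]]
    toks <- sim@truth$edgeTokens[[v]]
    if (!is.null(toks)) edgeTokens[[i]] <- toks
    if (v <= ntip) samples[[i]] <- tr$tip.label[v]
  }
  new("CladePhylogeny", parent = parent, edgeTokens = edgeTokens,
      samples = samples, labels = rep(NA_character_, length(order)),
      reference = "simref")
}

#' Write a simulation to disk
#'
#' Emits `sim.fasta` (root reference plus tips), `profiles.tsv` (one
#' sample per line) and `truth.json` (TMRCA, node ages, tip labels and
#' per-edge planted mutations, keyed by the child node id of the `phylo`
#' edge matrix).
#'
#' @param sim a [CladeSimulation-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing truth.json requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim@fasta, file.path(dir, "sim.fasta"))
  writeProfiles(sim@profiles, file.path(dir, "profiles.tsv"))
  tr <- sim@truth
  planted <- tr$edgeTokens
  names(planted) <- as.character(seq_along(planted))
  jsonlite::write_json(
    list(tmrca_years = tr$tmrcaYears,
         node_ages_years = tr$nodeAgesYears,
         tip_labels = tr$tree$tip.label,
         edge_parent = tr$tree$edge[, 1L],
         edge_child = tr$tree$edge[, 2L],
         edge_mutations = planted[vapply(planted, length, 1L) > 0L]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Construct synthetic population surveys with known frequencies
#'
#' Builds [PopulationSurvey-class] fixtures in which each population
#' contains a requested number of carriers of each clade's HVS-I motif
#' plus background haplotypes that avoid every requested motif position,
#' so [surveyFrequencies()] recovers the requested table exactly.  The
#' requested clades must have non-nested HVS-I motifs (otherwise a carrier
#' of one clade would also count for another and exact recovery is
#' impossible by construction).
#'
#' @param carriers matrix or data.frame of carrier counts, one row per
#'   population (rownames are population names), one column per clade
#'   (colnames are clade names).
#' @param n surveyed individuals per population (recycled).
#' @param defs a [HaplogroupTree-class].
#' @param seed mandatory RNG seed (background haplotypes, coordinates).
#' @param backgroundPerPop extra non-carrier haplotypes listed per
#'   population (default: fill up to `n`).
#' @return list of [PopulationSurvey-class].
#' @export
makeSurvey <- function(carriers, n, defs, seed, backgroundPerPop = NULL) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  carriers <- as.matrix(carriers)
  if (any(carriers < 0)) stop("carrier counts must be >= 0")
  pops <- rownames(carriers)
  if (is.null(pops)) pops <- paste0("pop", seq_len(nrow(carriers)))
  clades <- colnames(carriers)
  n <- rep_len(as.integer(n), nrow(carriers))
  if (any(rowSums(carriers) > n)) stop("more carriers than surveyed individuals")

  motifs <- lapply(clades, function(cl) cumulativeMotif(defs, cl, "HVS-I"))
  names(motifs) <- clades
  nd <- !vapply(clades, function(cl) .hvs1Distinct(defs, cl),
                logical(1L))
  if (any(nd))
    stop("clade(s) with no HVS-I-visible motif of their own cannot seed ",
         "a survey: ", paste(clades[nd], collapse = ", "))
  for (a in clades) for (b in clades)
    if (a != b && all(motifs[[a]] %in% motifs[[b]]))
      stop("nested HVS-I motifs (", a, " within ", b,
           "): exact recovery impossible")

  used <- unique(unlist(lapply(motifs, function(m) parseVariant(m)$position)))
  free <- setdiff(seq(.HVS1_START, .HVS1_END), used)

  out <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    haps <- list()
    for (cl in clades)
      haps <- c(haps, rep(list(motifs[[cl]]), carriers[i, cl]))
    nbg <- if (is.null(backgroundPerPop)) n[i] - length(haps)
    else min(backgroundPerPop, n[i] - length(haps))
    if (nbg > 0L)
      haps <- c(haps, lapply(seq_len(nbg), function(j)
        as.character(sort(sample(free, sample(1:3, 1L))))))
    out[[i]] <- populationSurvey(pops[i],
                                 latitude = runif(1L, -55, 70),
                                 longitude = runif(1L, -180, 180),
                                 n = n[i], haplotypes = haps)
  }
  names(out) <- pops
  out
}
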