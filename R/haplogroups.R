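# Haplogroup definition trees, cumulative motifs, classification, surveys.

#' Construct a haplogroup definition tree
#'
#' @param defs data.frame with columns `name`, `parent` (empty string for
#'   the root), `motif` (space-separated variant tokens; empty for the
#'   root) and optionally `source` (provenance tag per clade:
#'   `"printed"`, `"curated"` or `"placeholder"`).
#' @return a [HaplogroupTree-class].
#' @examples
#' haplogroupTree(data.frame(
#'   name = c("N", "W"), parent = c("", "N"),
#'   motif = c("", "204 207 16292"), source = "curated"))
#' @export
haplogroupTree <- function(defs) {
  defs <- as.data.frame(defs, stringsAsFactors = FALSE)
  if (is.null(defs$source)) defs$source <- "curated"
  defs$parent[is.na(defs$parent) | defs$parent == "-"] <- ""
  defs$motif[is.na(defs$motif) | defs$motif == "-"] <- ""
  motifs <- lapply(defs$motif, function(m)
    if (nzchar(trimws(m))) .canonicalTokens(strsplit(trimws(m), "[ ,]+")[[1L]])
    else character())
  names(motifs) <- defs$name
  new("HaplogroupTree",
      defs = defs[, c("name", "parent", "source")],
      motifs = motifs, rootName = defs$name[defs$parent == ""][1L])
}

#' Read a haplogroup definition table
#'
#' Tab-separated with a header line: `name`, `parent`, `motif`
#' (space-separated tokens, "-" for none), `source`.
#'
#' @param file path.
#' @return a [HaplogroupTree-class].
#' @export
readHaplogroupDefs <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, comment.char = "#")
  haplogroupTree(d)
}

#' Built-in haplogroup I / W definition tree
#'
#' A curated definition tree for the West-Eurasian mtDNA haplogroups I
#' (within N1a1b) and W and their named subclades, rooted at haplogroup N.
#' Branch motifs documented in the phylogenetic literature are tagged
#' `"printed"` or `"curated"`; clades whose defining mutations are not
#' reproduced here carry a synthetic single-site placeholder marker in an
#' otherwise unused coding-region range (tagged `"placeholder"`), which
#' keeps the tree structurally complete and classification well-behaved
#' but must not be mistaken for real PhyloTree motifs — hence the
#' `_synthetic` suffix of the shipped file.
#'
#' @return a [HaplogroupTree-class].
#' @export
builtinHaplogroups <- function() {
  readHaplogroupDefs(system.file("extdata", "haplogroups_iw_synthetic.tsv",
                                 package = "mitochron", mustWork = TRUE))
}

.claPath <- function(x, clade) {
  pa <- setNames(x@defs$parent, x@defs$name)
  if (!clade %in% names(pa)) stop("unknown clade: ", clade)
  path <- character()
  cur <- clade
  while (cur != "") {
    path <- c(cur, path)
    cur <- pa[[cur]]
  }
  path
}

# TRUE when the clade's HVS-I-restricted cumulative motif differs from
# its parent's (the clade is distinguishable from the parent in HVS-I;
# non-empty at the root).
.hvs1Distinct <- function(x, clade) {
  cum <- cumulativeMotif(x, clade, "HVS-I")
  if (length(cum) == 0L) return(FALSE)
  pa <- x@defs$parent[x@defs$name == clade]
  if (pa == "") return(TRUE)
  !setequal(cum, cumulativeMotif(x, pa, "HVS-I"))
}

#' Depth of a clade below the root
#'
#' @param x a [HaplogroupTree-class].
#' @param clade clade name.
#' @return integer depth (root = 0).
#' @export
cladeDepth <- function(x, clade) length(.claPath(x, clade)) - 1L

# Apply one motif to a cumulative state (named token map keyed by
# position/insert-index).  A back mutation at a position removes the
# earlier event there and is itself dropped; a second ordinary event at an
# already-derived position replaces the earlier one.
.applyMotif <- function(state, tokens) {
  if (length(tokens) == 0L) return(state)
  v <- parseVariant(tokens)
  keys <- .posKey(v)
  for (i in seq_len(nrow(v))) {
    if (v$back_mutation[i]) state[[keys[i]]] <- NULL
    else state[[keys[i]]] <- v$token[i]
  }
  state
}

.stateTokens <- function(state) {
  if (length(state) == 0L) return(character())
  .canonicalTokens(unlist(state, use.names = FALSE))
}

#' Cumulative motif of a clade
#'
#' Union of the branch motifs from the root down to `clade`, with back
#' mutations cancelling earlier events at the same position (both the
#' reversion and the reverted event drop out), optionally restricted to a
#' genomic region.
#'
#' @param x a [HaplogroupTree-class].
#' @param clade clade name.
#' @param region restrict the returned tokens to this region (see
#'   [inRegion()]).
#' @return character vector of canonical tokens.
#' @export
cumulativeMotif <- function(x, clade, region = "full_genome") {
  path <- .claPath(x, clade)
  state <- list()
  for (cl in path) state <- .applyMotif(state, x@motifs[[cl]])
  toks <- .stateTokens(state)
  if (length(toks) && region != "full_genome")
    toks <- toks[inRegion(parseVariant(toks)$position, region)]
  toks
}

# Cumulative (region-restricted) motifs for all clades in one DFS pass.
.allCumulativeMotifs <- function(x, region = "full_genome") {
  children <- split(x@defs$name, x@defs$parent)
  out <- vector("list", nrow(x@defs))
  names(out) <- x@defs$name
  recurse <- function(clade, state) {
    state <- .applyMotif(state, x@motifs[[clade]])
    toks <- .stateTokens(state)
    if (length(toks) && region != "full_genome")
      toks <- toks[inRegion(parseVariant(toks)$position, region)]
    out[[clade]] <<- toks
    for (ch in children[[clade]]) recurse(ch, state)
  }
  recurse(x@rootName, list())
  out
}

#' Classify a variant profile into a haplogroup
#'
#' Scores every clade by `matched - missing` over its cumulative motif,
#' where both the motif and the profile are restricted to the profile's
#' covered region (so HVS-I haplotypes are judged only on control-region
#' evidence).  Sample variants on no motif are private and not penalised.
#' Clades whose restricted cumulative motif is identical to their parent's
#' are not separate candidates (they are indistinguishable in the covered
#' region).  Ties are broken by greater depth, then by the
#' stability-weighted matched count (hypermutable sites count less), then
#' by name; the result is deterministic.
#'
#' @param profile a [VariantProfile-class].
#' @param defs a [HaplogroupTree-class].
#' @param weights site-stability weights, see [hotspotWeights()].
#' @return a [ClassificationResult-class].
#' @examples
#' defs <- builtinHaplogroups()
#' p <- variantProfile("anc", c("16192", "16223", "16292", "16325"),
#'                     region = "HVS-I")
#' classifyProfile(p, defs)
#' @export
classifyProfile <- function(profile, defs, weights = hotspotWeights()) {
  if (nrow(defs@defs) == 0L) stop("empty definition tree")
  region <- profile@region
  cums <- .allCumulativeMotifs(defs, region)
  ptoks <- profile@tokens
  if (region != "full_genome")
    ptoks <- ptoks[inRegion(parseVariant(ptoks)$position, region)]
  pa <- setNames(defs@defs$parent, defs@defs$name)
  nm <- defs@defs$name
  depth <- vapply(nm, function(cl) cladeDepth(defs, cl), integer(1L))
  candidate <- vapply(nm, function(cl) {
    cl == defs@rootName || !setequal(cums[[cl]], cums[[pa[[cl]]]])
  }, logical(1L))
  matched <- integer(length(nm)); missing <- integer(length(nm))
  wmatched <- numeric(length(nm))
  for (i in seq_along(nm)) {
    cum <- cums[[nm[i]]]
    hit <- cum %in% ptoks
    matched[i] <- sum(hit)
    missing[i] <- sum(!hit)
    wmatched[i] <- if (matched[i])
      sum(.siteWeight(parseVariant(cum[hit])$position, weights)) else 0
  }
  score <- matched - missing
  tab <- data.frame(clade = nm, depth = depth, matched = matched,
                    missing = missing, score = score, candidate = candidate,
                    stringsAsFactors = FALSE, row.names = NULL)
  idx <- which(candidate)
  ord <- idx[order(-score[idx], -depth[idx], -wmatched[idx], nm[idx])]
  best <- ord[1L]
  new("ClassificationResult", sampleID = profile@sampleID,
      bestClade = nm[best], matched = matched[best],
      missing = missing[best],
      private = length(setdiff(ptoks, cums[[nm[best]]])),
      score = score[best],
      table = tab[order(-tab$score, -tab$depth, tab$clade), ])
}

#' @rdname classifyProfile
#' @param profiles list of [VariantProfile-class].
#' @return `classifyProfiles`: data.frame with one row per profile.
#' @export
classifyProfiles <- function(profiles, defs, weights = hotspotWeights()) {
  rows <- lapply(profiles, function(p) {
    r <- classifyProfile(p, defs, weights)
    data.frame(sample_id = r@sampleID, haplogroup = r@bestClade,
               matched = r@matched, missing = r@missing,
               private = r@private, score = r@score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a population survey
#'
#' @param population population name.
#' @param latitude,longitude decimal degrees.
#' @param n number of individuals surveyed.
#' @param haplotypes list of HVS-I token vectors, one per carrier of a
#'   haplotype of interest (at most `n`).
#' @return a [PopulationSurvey-class].
#' @export
populationSurvey <- function(population, latitude, longitude, n,
                             haplotypes = list()) {
  new("PopulationSurvey", population = as.character(population),
      latitude = as.numeric(latitude), longitude = as.numeric(longitude),
      n = as.integer(n),
      haplotypes = lapply(haplotypes, .canonicalTokens))
}

#' Read a survey table
#'
#' Tab-separated with header `population`, `lat`, `lon`, `n`, `haplotype`
#' (space-separated HVS-I tokens); one row per carrier, population
#' metadata repeated.  A row with haplotype "-" contributes no carrier
#' (used for populations with none).
#'
#' @param file path.
#' @return list of [PopulationSurvey-class] in first-appearance order.
#' @export
readSurvey <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, comment.char = "#")
  lapply(split(d, factor(d$population, levels = unique(d$population))),
         function(g) {
           haps <- lapply(g$haplotype[g$haplotype != "-"], function(h)
             strsplit(trimws(h), "[ ,]+")[[1L]])
           populationSurvey(g$population[1L], g$lat[1L], g$lon[1L], g$n[1L],
                            haps)
         })
}

#' Per-population haplogroup frequencies from HVS-I data
#'
#' A survey individual carries a clade when its HVS-I haplotype contains
#' every token of the clade's HVS-I-restricted cumulative motif.  A clade
#' whose restricted motif adds nothing over its parent's (e.g. one
#' defined solely by coding-region mutations, like W3 with its single
#' transition at 1406) is indistinguishable from its parent in HVS-I and
#' cannot be assessed from control-region data; it is flagged and
#' reported as NA.
#'
#' @param surveys list of [PopulationSurvey-class].
#' @param defs a [HaplogroupTree-class].
#' @param clades clade names to tabulate.
#' @return data.frame with population, latitude, longitude, n and one
#'   percentage column per clade, rows in input order; the
#'   `"nonAssessable"` attribute lists clades without HVS-I motifs.
#'   Populations with `n = 0` are skipped with a warning.
#' @export
surveyFrequencies <- function(surveys, defs, clades) {
  motifs <- lapply(clades, function(cl) cumulativeMotif(defs, cl, "HVS-I"))
  names(motifs) <- clades
  assessable <- vapply(clades, function(cl) .hvs1Distinct(defs, cl),
                       logical(1L))
  if (any(!assessable))
    warning("clade(s) with no HVS-I-visible motif of their own cannot be ",
            "assessed from control-region data: ",
            paste(clades[!assessable], collapse = ", "))
  rows <- lapply(surveys, function(s) {
    if (s@n == 0L) {
      warning("skipping population with n = 0: ", s@population)
      return(NULL)
    }
    freq <- vapply(clades, function(cl) {
      if (!assessable[[cl]]) return(NA_real_)
      carriers <- sum(vapply(s@haplotypes, function(h)
        all(motifs[[cl]] %in% h), logical(1L)))
      100 * carriers / s@n
    }, numeric(1L))
    cbind(data.frame(population = s@population, latitude = s@latitude,
                     longitude = s@longitude, n = s@n,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(freq), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nonAssessable") <- clades[!assessable]
  out
}
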