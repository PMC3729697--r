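# S4 classes for the package's central objects.

#' VariantProfile: a sample's mtDNA variants relative to a reference
#'
#' Holds the canonical variant tokens of one sample relative to a named
#' reference sequence, together with the genomic region the sample covers.
#' Within one profile a (position, insertion-index) pair is unique.
#'
#' @slot sampleID single sample identifier.
#' @slot reference reference name the tokens are relative to (e.g. "rCRS").
#' @slot tokens canonical variant tokens, sorted by position.
#' @slot region one of "full_genome", "HVS-I", "control_region".
#' @seealso [variantProfile()]
#' @export
setClass("VariantProfile",
  representation(sampleID = "character", reference = "character",
                 tokens = "character", region = "character"))

setValidity("VariantProfile", function(object) {
  msg <- character()
  if (length(object@sampleID) != 1L) msg <- c(msg, "sampleID must be length 1")
  if (length(object@reference) != 1L) msg <- c(msg, "reference must be length 1")
  if (!object@region %in% .REGIONS)
    msg <- c(msg, paste("region must be one of", paste(.REGIONS, collapse = ", ")))
  v <- tryCatch(parseVariant(object@tokens), error = function(e) e)
  if (inherits(v, "error")) return(conditionMessage(v))
  key <- paste(v$position, ifelse(is.na(v$insert_index), 0L, v$insert_index))
  if (anyDuplicated(key))
    msg <- c(msg, "duplicated (position, insertion-index) within one profile")
  if (object@region != "full_genome" && !all(inRegion(v$position, object@region)))
    msg <- c(msg, sprintf("variant positions outside declared region '%s'",
                          object@region))
  if (length(msg)) msg else TRUE
})

#' SiteMask: variant identities excluded from distances and dating
#'
#' @slot tokens variant tokens defining the mask.  A bare-position token
#'   masks every event at that position; a token with a base letter masks
#'   only that derived state.
#' @seealso [defaultSiteMask()], [applyMask()]
#' @export
setClass("SiteMask", representation(tokens = "character"))

setValidity("SiteMask", function(object) {
  v <- tryCatch(parseVariant(object@tokens), error = function(e) e)
  if (inherits(v, "error")) conditionMessage(v) else TRUE
})

#' HaplogroupTree: a rooted tree of haplogroup definitions
#'
#' Each clade has a unique name, a parent (the root's parent is ""), a
#' motif (variant tokens on the branch from the parent) and a provenance
#' tag (`"printed"`, `"curated"` or `"placeholder"` for synthetic stand-in
#' markers).
#'
#' @slot defs data.frame with columns name, parent, source.
#' @slot motifs named list of character vectors (tokens per clade).
#' @slot rootName name of the root clade.
#' @seealso [haplogroupTree()], [builtinHaplogroups()], [cumulativeMotif()]
#' @export
setClass("HaplogroupTree",
  representation(defs = "data.frame", motifs = "list", rootName = "character"))

setValidity("HaplogroupTree", function(object) {
  d <- object@defs
  msg <- character()
  if (!all(c("name", "parent", "source") %in% names(d)))
    return("defs needs columns name, parent, source")
  if (anyDuplicated(d$name)) msg <- c(msg, "duplicated clade names")
  root <- d$name[d$parent == ""]
  if (length(root) != 1L) msg <- c(msg, "exactly one root (parent == \"\") required")
  known <- d$parent == "" | d$parent %in% d$name
  if (!all(known))
    msg <- c(msg, paste("unknown parent(s):", paste(d$parent[!known], collapse = ", ")))
  if (!setequal(names(object@motifs), d$name))
    msg <- c(msg, "motifs must be named by clade name")
  # cycle check: every clade must reach the root
  if (!length(msg)) {
    pa <- setNames(d$parent, d$name)
    for (nm in d$name) {
      seen <- character(); cur <- nm
      while (cur != "") {
        if (cur %in% seen) return(paste("cycle through", cur))
        seen <- c(seen, cur); cur <- pa[[cur]]
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' CladePhylogeny: rooted haplotype tree with edge-attached mutations
#'
#' Nodes are stored in topological order (the parent of node i has a lower
#' index; node 1 is the root).  Each non-root node carries the mutation
#' tokens of the edge leading into it; reversions are rendered with a
#' trailing "@".  Samples may sit at any node, including internal nodes
#' (ancestral haplotypes).
#'
#' @slot parent integer vector; parent[1] is NA (root).
#' @slot edgeTokens list of character vectors, edge into each node.
#' @slot samples list of character vectors, sample ids attached per node.
#' @slot labels optional haplogroup labels per node (NA when unset).
#' @slot reference reference name shared by the input profiles.
#' @seealso [buildCladeTree()], [replayProfiles()], [rhoSigma()]
#' @export
setClass("CladePhylogeny",
  representation(parent = "integer", edgeTokens = "list", samples = "list",
                 labels = "character", reference = "character"))

setValidity("CladePhylogeny", function(object) {
  n <- length(object@parent)
  msg <- character()
  if (n < 1L || !is.na(object@parent[1L])) msg <- c(msg, "node 1 must be the root")
  if (n > 1L) {
    pa <- object@parent[-1L]
    if (anyNA(pa) || any(pa >= seq(2L, n) | pa < 1L))
      msg <- c(msg, "parents must precede children (topological order)")
  }
  if (length(object@edgeTokens) != n || length(object@samples) != n ||
      length(object@labels) != n)
    msg <- c(msg, "edgeTokens, samples and labels must have one entry per node")
  if (length(object@edgeTokens) >= 1L && length(object@edgeTokens[[1L]]) != 0L)
    msg <- c(msg, "the root carries no edge mutations")
  if (length(msg)) msg else TRUE
})

#' ClockModel: substitutions-to-years conversion for whole mitogenomes
#'
#' A strictly increasing mapping from whole-molecule substitution counts to
#' ages in ky, corrected for the time-dependent removal of mildly
#' deleterious mutations by purifying selection, plus its inverse.
#' Negative distances (which arise when normal-theory confidence bounds
#' cross zero) are converted by odd extension.
#'
#' @slot forward function(substitutions) -> age in ky.
#' @slot inverse function(age in ky) -> substitutions.
#' @slot provenance "anchor-calibrated" or "parametric-fit".
#' @slot anchors the aggregated calibration anchors actually interpolated.
#' @seealso [correctedClock()], [clockConvert()]
#' @export
setClass("ClockModel",
  representation(forward = "function", inverse = "function",
                 provenance = "character", anchors = "data.frame"))

setValidity("ClockModel", function(object) {
  f <- object@forward
  if (abs(f(0)) > 1e-9) return("forward(0) must be 0")
  g <- seq(0, 20, by = 0.25)
  if (any(diff(f(g)) <= 0)) return("forward must be strictly increasing")
  TRUE
})

#' AgeEstimate: a mutational distance with its dispersion
#'
#' Produced by [rhoSigma()] (method "rho": mean root-to-tip substitutions
#' with the heuristic standard error) or [mlDivergence()] (method "ml":
#' clock-constrained Poisson maximum-likelihood divergence with a
#' curvature-based standard error).
#'
#' @slot clade clade label (may be the node index as character).
#' @slot method "rho" or "ml".
#' @slot n number of samples in the clade.
#' @slot distance point estimate in substitutions.
#' @slot dispersion standard error in substitutions (NA when undefined,
#'   e.g. ML on a single-sample clade).
#' @export
setClass("AgeEstimate",
  representation(clade = "character", method = "character", n = "integer",
                 distance = "numeric", dispersion = "numeric"))

setValidity("AgeEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("rho", "ml")) msg <- c(msg, "method must be rho or ml")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@distance < 0) msg <- c(msg, "distance must be >= 0")
  if (!is.na(object@dispersion) && object@dispersion < 0)
    msg <- c(msg, "dispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AgeResult: a dated clade with normal-theory confidence bounds
#'
#' @slot clade,method,n see [AgeEstimate-class].
#' @slot distance,dispersion substitutions.
#' @slot ageKy point age in ky.
#' @slot ciLowKy,ciHighKy 95% bounds in ky; the lower bound may be
#'   negative (distance bounds crossing zero are converted as-is).
#' @seealso [ageWithCI()]
#' @export
setClass("AgeResult",
  representation(clade = "character", method = "character", n = "integer",
                 distance = "numeric", dispersion = "numeric",
                 ageKy = "numeric", ciLowKy = "numeric", ciHighKy = "numeric"))

setValidity("AgeResult", function(object) {
  ok <- is.na(object@ciLowKy) ||
    (object@ciLowKy <= object@ageKy && object@ageKy <= object@ciHighKy)
  if (!ok) "confidence bounds must bracket the point age" else TRUE
})

#' ClassificationResult: best haplogroup call for one profile
#'
#' @slot sampleID sample identifier.
#' @slot bestClade name of the highest-scoring clade.
#' @slot matched,missing counts over the best clade's cumulative motif
#'   (restricted to the profile's region).
#' @slot private sample variants on no motif along the best clade's path.
#' @slot score matched - missing.
#' @slot table per-candidate score table (data.frame).
#' @export
setClass("ClassificationResult",
  representation(sampleID = "character", bestClade = "character",
                 matched = "integer", missing = "integer", private = "integer",
                 score = "numeric", table = "data.frame"))

#' PopulationSurvey: HVS-I haplotypes sampled from one population
#'
#' @slot population population name.
#' @slot latitude,longitude decimal degrees.
#' @slot n number of individuals surveyed (>= number of listed haplotypes).
#' @slot haplotypes list of HVS-I token vectors, one per carrier.
#' @export
setClass("PopulationSurvey",
  representation(population = "character", latitude = "numeric",
                 longitude = "numeric", n = "integer", haplotypes = "list"))

setValidity("PopulationSurvey", function(object) {
  msg <- character()
  if (object@n < length(object@haplotypes))
    msg <- c(msg, "n must be >= number of listed haplotypes")
  if (abs(object@latitude) > 90) msg <- c(msg, "latitude out of range")
  if (abs(object@longitude) > 180) msg <- c(msg, "longitude out of range")
  if (length(msg)) msg else TRUE
})

#' CladeSimulation: a simulated clade with full truth records
#'
#' @slot truth list with the scaled genealogy (`tree`, an ape phylo with
#'   branch lengths in years), `tmrcaYears`, `nodeAgesYears`, per-edge
#'   planted mutation tokens (`edgeTokens`, keyed by child node id) and the
#'   root sequence.
#' @slot profiles list of [VariantProfile-class], one per tip.
#' @slot fasta `DNAStringSet` with the root reference and the tip
#'   sequences.
#' @seealso [simulateClade()]
#' @export
setClass("CladeSimulation",
  representation(truth = "list", profiles = "list", fasta = "ANY"))
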