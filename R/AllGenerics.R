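# Generics and small accessor/show methods.

#' @rdname VariantProfile-class
#' @param object,x a `VariantProfile`.
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))
#' @rdname VariantProfile-class
#' @export
setGeneric("referenceName", function(x) standardGeneric("referenceName"))
#' @rdname VariantProfile-class
#' @export
setGeneric("variantTokens", function(x) standardGeneric("variantTokens"))
#' @rdname VariantProfile-class
#' @export
setGeneric("profileRegion", function(x) standardGeneric("profileRegion"))

#' @export
setMethod("sampleID", "VariantProfile", function(x) x@sampleID)
#' @export
setMethod("referenceName", "VariantProfile", function(x) x@reference)
#' @export
setMethod("variantTokens", "VariantProfile", function(x) x@tokens)
#' @export
setMethod("profileRegion", "VariantProfile", function(x) x@region)

setMethod("show", "VariantProfile", function(object) {
  cat(sprintf("VariantProfile '%s' vs %s [%s], %d variant(s)\n",
              object@sampleID, object@reference, object@region,
              length(object@tokens)))
  if (length(object@tokens))
    cat(" ", paste(object@tokens, collapse = " "), "\n")
})

setMethod("show", "SiteMask", function(object) {
  cat("SiteMask:", if (length(object@tokens))
    paste(object@tokens, collapse = " ") else "(empty)", "\n")
})

#' @rdname HaplogroupTree-class
#' @param x a `HaplogroupTree`.
#' @export
setGeneric("cladeNames", function(x) standardGeneric("cladeNames"))
#' @export
setMethod("cladeNames", "HaplogroupTree", function(x) x@defs$name)

#' @rdname HaplogroupTree-class
#' @export
setGeneric("rootName", function(x) standardGeneric("rootName"))
#' @export
setMethod("rootName", "HaplogroupTree", function(x) x@rootName)

setMethod("show", "HaplogroupTree", function(object) {
  cat(sprintf("HaplogroupTree: %d clades rooted at '%s'\n",
              nrow(object@defs), object@rootName))
  src <- table(object@defs$source)
  cat("  motif provenance:",
      paste(sprintf("%s=%d", names(src), as.integer(src)), collapse = ", "), "\n")
})

#' @rdname CladePhylogeny-class
#' @param x a `CladePhylogeny`.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @export
setMethod("nodeCount", "CladePhylogeny", function(x) length(x@parent))

#' @rdname CladePhylogeny-class
#' @export
setGeneric("edgeMutations", function(x) standardGeneric("edgeMutations"))
#' @export
setMethod("edgeMutations", "CladePhylogeny", function(x) x@edgeTokens)

#' @rdname CladePhylogeny-class
#' @export
setGeneric("nodeSamples", function(x) standardGeneric("nodeSamples"))
#' @export
setMethod("nodeSamples", "CladePhylogeny", function(x) x@samples)

#' @rdname CladePhylogeny-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "CladePhylogeny", function(x)
  unlist(x@samples, use.names = FALSE))

setMethod("show", "CladePhylogeny", function(object) {
  cat(sprintf(
    "CladePhylogeny: %d nodes, %d samples, %d edge mutations (ref %s)\n",
    length(object@parent), length(sampleIds(object)),
    sum(lengths(object@edgeTokens)), object@reference))
})

setMethod("show", "ClockModel", function(object) {
  a <- object@anchors
  cat(sprintf("ClockModel (%s): %d anchors on [0, %.2f] substitutions\n",
              object@provenance, nrow(a), max(a$d)))
  cat(sprintf("  local pace: %.2f ky/substitution near 0, %.2f near %.1f\n",
              object@forward(0.5) / 0.5,
              (object@forward(10.5) - object@forward(9.5)), 10))
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf("AgeEstimate [%s] clade %s: n=%d, distance=%.3f, dispersion=%s\n",
              object@method, object@clade, object@n, object@distance,
              ifelse(is.na(object@dispersion), "NA",
                     sprintf("%.3f", object@dispersion))))
})

setMethod("show", "AgeResult", function(object) {
  cat(sprintf("%s [%s]: %.1f ky (95%% CI %.1f; %.1f), distance %.2f +/- %s\n",
              object@clade, object@method, object@ageKy, object@ciLowKy,
              object@ciHighKy, object@distance,
              ifelse(is.na(object@dispersion), "NA",
                     sprintf("%.2f", object@dispersion))))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "ClassificationResult '%s': %s (score %g; matched %d, missing %d, private %d)\n",
    object@sampleID, object@bestClade, object@score, object@matched,
    object@missing, object@private))
})

setMethod("show", "PopulationSurvey", function(object) {
  cat(sprintf("PopulationSurvey '%s' (%.1f, %.1f): n=%d, %d carrier haplotype(s)\n",
              object@population, object@latitude, object@longitude,
              object@n, length(object@haplotypes)))
})

setMethod("show", "CladeSimulation", function(object) {
  cat(sprintf("CladeSimulation: %d tips, TMRCA %.0f years, %d planted mutations\n",
              length(object@profiles), object@truth$tmrcaYears,
              sum(lengths(object@truth$edgeTokens))))
})

#' @rdname applyMask
#' @export
setGeneric("applyMask", function(x, mask = defaultSiteMask())
  standardGeneric("applyMask"))
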