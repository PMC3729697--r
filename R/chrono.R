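# Coalescence dating: rho/sigma, clock-constrained Poisson ML divergence,
# the corrected molecular clock, and confidence intervals.

# Weighted pool-adjacent-violators: isotonic (non-decreasing) regression.
.pava <- function(y, w) {
  n <- length(y)
  vals <- as.numeric(y); wts <- as.numeric(w); sizes <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; sizes[m] <- 1L
    while (m > 1L && vals[m - 1L] > vals[m]) {
      wv <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (vals[m - 1L] * wts[m - 1L] + vals[m] * wts[m]) / wv
      wts[m - 1L] <- wv
      sizes[m - 1L] <- sizes[m - 1L] + sizes[m]
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], sizes[seq_len(m)])
}

.clockPairs <- function(tab) {
  ivw <- function(disp) 1 / pmax(disp, 0.15)^2
  direct <- rbind(
    data.frame(d = tab$ml, t = tab$mlage, w = ivw(tab$mlse)),
    data.frame(d = tab$rho, t = tab$rhoage, w = ivw(tab$sigma)))
  ci <- rbind(
    data.frame(d = tab$ml - 1.96 * tab$mlse, t = tab$mllo),
    data.frame(d = tab$ml + 1.96 * tab$mlse, t = tab$mlhi),
    data.frame(d = tab$rho - 1.96 * tab$sigma, t = tab$rholo),
    data.frame(d = tab$rho + 1.96 * tab$sigma, t = tab$rhohi))
  # CI-endpoint pairs carry a homoscedastic distance error (dominated by
  # the rounding of the printed dispersion), so they get a flat weight and
  # serve only to fill regions with no direct anchor nearby.
  gap <- vapply(ci$d, function(x) min(abs(x - c(direct$d, 0))), numeric(1L))
  ci <- ci[gap > 0.1 & ci$d > 0, , drop = FALSE]
  ci$w <- 1
  rbind(direct, ci)
}

.aggregateAnchors <- function(pairs) {
  pairs <- pairs[pairs$d > 0, , drop = FALSE]
  pairs <- rbind(data.frame(d = 0, t = 0, w = 1000), pairs)
  key <- sprintf("%.6f", pairs$d)
  agg <- do.call(rbind, lapply(split(pairs, key), function(g)
    data.frame(d = g$d[1L], t = sum(g$t * g$w) / sum(g$w), w = sum(g$w))))
  agg <- agg[order(agg$d), , drop = FALSE]
  agg$t <- .pava(agg$t, agg$w)
  # strictify flat stretches so the mapping is invertible
  agg$t <- agg$t + cumsum(c(0, as.numeric(diff(agg$t) <= 0))) * 1e-9
  rownames(agg) <- NULL
  agg
}

.monotoneInterpolator <- function(agg) {
  f <- splinefun(agg$d, agg$t, method = "monoH.FC")
  nA <- nrow(agg)
  slopeHi <- (agg$t[nA] - agg$t[nA - 1L]) / (agg$d[nA] - agg$d[nA - 1L])
  dmax <- agg$d[nA]
  tmax <- agg$t[nA]
  function(d) {
    s <- sign(d)
    d <- abs(d)
    out <- ifelse(d > dmax, tmax + (d - dmax) * slopeHi, f(pmin(d, dmax)))
    s * out
  }
}

.parametricClock <- function(tab) {
  ivw <- function(disp) 1 / pmax(disp, 0.15)^2
  pairs <- rbind(
    data.frame(d = tab$ml, t = tab$mlage, w = ivw(tab$mlse)),
    data.frame(d = tab$rho, t = tab$rhoage, w = ivw(tab$sigma)))
  # d(t) = a*t + b*(1 - exp(-t/tau)): a constant neutral accumulation rate
  # plus a transient excess of young, not-yet-purged mildly deleterious
  # mutations that decays on timescale tau — the signature shape of a
  # purifying-selection-corrected clock.
  obj <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L]); tau <- exp(p[3L])
    dpred <- a * pairs$t + b * (1 - exp(-pairs$t / tau))
    sum(pairs$w * (dpred - pairs$d)^2)
  }
  o <- optim(c(log(0.33), log(0.5), log(5)), obj, method = "BFGS",
             control = list(maxit = 500))
  p <- exp(o$par)
  dfun <- function(t) p[1L] * t + p[2L] * (1 - exp(-t / p[3L]))
  fwd <- function(d) {
    s <- sign(d)
    d <- abs(d)
    s * vapply(d, function(di) {
      if (di <= 0) return(0)
      uniroot(function(t) dfun(t) - di, c(0, 2000), tol = 1e-10)$root
    }, numeric(1L))
  }
  list(forward = fwd, params = p)
}

#' The purifying-selection-corrected molecular clock
#'
#' Converts whole-mtDNA substitution distances (hotspot sites excluded)
#' into ages in ky.  Because mildly deleterious mutations are removed only
#' slowly by purifying selection, the apparent substitution rate is higher
#' in young clades than in old ones: the conversion is non-linear, running
#' at roughly 2.5 ky per substitution near the present and close to 3 ky
#' per substitution beyond ten substitutions.
#'
#' Two constructions are available.  `"anchors"` (the default and primary
#' mode) interpolates the published (distance, age) anchor pairs of
#' [ageAnchorTable()] — direct pairs weighted by the inverse squared
#' printed dispersion (floored at 0.15), CI-endpoint pairs added at flat
#' weight only where no direct anchor lies within 0.1 substitutions —
#' aggregated per distance, monotonised by weighted pool-adjacent
#' violators and interpolated with a monotone Hermite spline (linear
#' continuation beyond the last anchor).  `"parametric"` fits the
#' three-parameter form `d(t) = a t + b (1 - exp(-t/tau))` (constant
#' neutral rate plus an exponentially decaying excess of unpurged
#' mutations) to the direct anchors and inverts it numerically.  The
#' provenance tag of the returned model records which construction is
#' active.
#'
#' Negative distances, which arise when normal-theory confidence bounds
#' cross zero, are converted by odd extension (`f(-d) = -f(d)`).
#'
#' @param method `"anchors"` or `"parametric"`.
#' @return a [ClockModel-class].
#' @examples
#' clk <- correctedClock()
#' clockConvert(clk, c(0.7, 6.8, 10.3))
#' @export
correctedClock <- function(method = c("anchors", "parametric")) {
  method <- match.arg(method)
  tab <- ageAnchorTable()
  if (method == "anchors") {
    agg <- .aggregateAnchors(.clockPairs(tab))
    fwd <- .monotoneInterpolator(agg)
    prov <- "anchor-calibrated"
  } else {
    fitted <- .parametricClock(tab)
    fwd <- fitted$forward
    agg <- .aggregateAnchors(rbind(
      data.frame(d = tab$ml, t = tab$mlage, w = 1),
      data.frame(d = tab$rho, t = tab$rhoage, w = 1)))
    prov <- "parametric-fit"
  }
  inv <- function(ky) {
    s <- sign(ky)
    ky <- abs(ky)
    s * vapply(ky, function(k) {
      if (k <= 0) return(0)
      hi <- 30
      while (fwd(hi) < k) hi <- hi * 2
      uniroot(function(d) fwd(d) - k, c(0, hi), tol = 1e-10)$root
    }, numeric(1L))
  }
  new("ClockModel", forward = fwd, inverse = inv, provenance = prov,
      anchors = agg)
}

#' Convert a mutational distance to an age
#'
#' @param model a [ClockModel-class].
#' @param distance substitutions (whole mitogenome, hotspot sites
#'   excluded).  Negative values are an error unless `allowNegative`
#'   (confidence bounds crossing zero are converted by odd extension).
#' @param allowNegative convert negative distances instead of failing.
#' @return age(s) in ky.
#' @examples
#' clockConvert(correctedClock(), 6.8)
#' @export
clockConvert <- function(model, distance, allowNegative = FALSE) {
  if (!allowNegative && any(distance < 0))
    stop("negative mutational distance")
  model@forward(distance)
}

#' Invert the clock: age in ky to expected substitutions
#'
#' @param model a [ClockModel-class].
#' @param ageKy age(s) in ky.
#' @return substitutions.
#' @export
clockInvert <- function(model, ageKy) model@inverse(ageKy)

# Substitution-type events on an edge (indels excluded from dating).
.substitutionCount <- function(tokens) {
  if (length(tokens) == 0L) return(0L)
  v <- parseVariant(sub("@$", "", tokens))
  sum(!v$var_class %in% c("insertion", "deletion"))
}

#' Rho statistic with heuristic standard error
#'
#' `rho` is the mean number of substitutions from the clade's root
#' haplotype to each of its `n` samples.  The heuristic standard error is
#' `sigma^2 = sum_e (n_e^2 m_e) / n^2` over the clade's edges, where `m_e`
#' is the edge's substitution count and `n_e` the number of samples below
#' it — the exact Poisson variance of rho conditional on the genealogy.
#' On a star tree this reduces to `sigma = sqrt(rho / n)`.
#'
#' @param tree a [CladePhylogeny-class] (mask already applied by
#'   [buildCladeTree()]; indels are excluded here).
#' @param node clade root node (default: tree root).
#' @param clade label recorded in the result.
#' @return an [AgeEstimate-class] with method `"rho"`.
#' @export
rhoSigma <- function(tree, node = 1L, clade = as.character(node)) {
  below <- .samplesBelowCount(tree)
  n <- below[node]
  if (n < 1L) stop("empty clade: no samples at or below node ", node)
  nodes <- .subtreeNodes(tree, node)
  edges <- setdiff(nodes, node)
  m <- vapply(tree@edgeTokens[edges], .substitutionCount, integer(1L))
  ne <- below[edges]
  rho <- if (length(edges)) sum(m * ne) / n else 0
  sigma <- if (length(edges)) sqrt(sum(ne^2 * m)) / n else 0
  new("AgeEstimate", clade = clade, method = "rho", n = as.integer(n),
      distance = rho, dispersion = sigma)
}

#' Clock-constrained Poisson maximum-likelihood divergence
#'
#' Estimates the expected number of substitutions from the clade root to
#' the present under a molecular clock on the fixed tree topology: node
#' heights are free parameters (every root-to-sample path has the same
#' total expected length), each edge's observed substitution count is
#' Poisson with mean equal to its height span, and the root height `ml`
#' is the estimate.  The standard error comes from the curvature
#' (observed information) of the profile at the optimum.  On a star tree
#' the estimate equals rho exactly; a clade with one sample returns that
#' sample's count with an undefined (NA) standard error.
#'
#' @inheritParams rhoSigma
#' @return an [AgeEstimate-class] with method `"ml"`.
#' @export
mlDivergence <- function(tree, node = 1L, clade = as.character(node)) {
  below <- .samplesBelowCount(tree)
  n <- below[node]
  if (n < 1L) stop("empty clade: no samples at or below node ", node)
  nodes <- .subtreeNodes(tree, node)
  edges <- setdiff(nodes, node)
  m <- vapply(tree@edgeTokens[edges], .substitutionCount, integer(1L))

  if (n == 1L) {
    return(new("AgeEstimate", clade = clade, method = "ml", n = 1L,
               distance = sum(m), dispersion = NA_real_))
  }
  if (sum(m) == 0L) {
    return(new("AgeEstimate", clade = clade, method = "ml",
               n = as.integer(n), distance = 0, dispersion = 0))
  }

  # Local model: the clade root sits at height T (the estimate), sampled
  # present-day lineages (childless sample-bearing nodes) at height 0,
  # and every other internal node at a free height between its parent
  # and 0 (parameterised through a logistic fraction).  Samples attached
  # to nodes with descendants (ancestral haplotypes) contribute a
  # zero-count pendant of expected length equal to the node's height.
  idx <- setNames(seq_along(nodes), nodes)
  parentLoc <- c(NA_integer_,
                 vapply(edges, function(v) idx[[as.character(tree@parent[v])]],
                        integer(1L)))
  hasKids <- tabulate(parentLoc[!is.na(parentLoc)],
                      nbins = length(nodes)) > 0L
  nSamp <- lengths(tree@samples[nodes])
  tipLike <- !hasKids & seq_along(nodes) > 1L
  free <- which(hasKids & seq_along(nodes) > 1L)   # free-height internals
  edgeCount <- c(NA_integer_, m)                   # by local id
  pendant <- unlist(lapply(which(hasKids | seq_along(nodes) == 1L),
                           function(i) rep(i, nSamp[i])))

  negll <- function(par) {
    h <- numeric(length(nodes))
    h[1L] <- exp(par[1L])
    for (k in seq_along(free)) {
      i <- free[k]
      h[i] <- h[parentLoc[i]] * plogis(par[1L + k])
    }
    h[tipLike] <- 0
    nonroot <- seq_along(nodes)[-1L]
    lamE <- h[parentLoc[nonroot]] - h[nonroot]
    lamP <- h[pendant]
    mm <- edgeCount[nonroot]
    ll <- sum(ifelse(mm > 0, mm * log(pmax(lamE, 1e-12)), 0)) -
      sum(lamE) - sum(lamP)
    -ll
  }
  init <- c(log(max(sum(m) / n, 0.5)), rep(0, length(free)))
  fit <- optim(init, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  # restart once from the optimum to polish convergence
  fit <- optim(fit$par, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  ml <- exp(fit$par[1L])
  # profile-likelihood curvature in log T (nuisance heights re-optimised
  # at each evaluation; robust to zero-count subtrees whose heights sit
  # at their boundaries), then the delta method back to the T scale
  se <- tryCatch({
    prof <- function(logT) {
      if (length(free) == 0L) return(-negll(logT))
      o <- optim(fit$par[-1L], function(th) negll(c(logT, th)),
                 method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-12))
      -o$value
    }
    lt <- fit$par[1L]
    dlt <- 0.1
    d2 <- (prof(lt + dlt) - 2 * prof(lt) + prof(lt - dlt)) / dlt^2
    if (!is.finite(d2) || d2 >= 0) NA_real_ else ml * sqrt(-1 / d2)
  }, error = function(e) NA_real_)
  new("AgeEstimate", clade = clade, method = "ml", n = as.integer(n),
      distance = ml, dispersion = se)
}

#' Convert an estimate to an age with 95% confidence bounds
#'
#' Normal-theory bounds on the substitution scale
#' (`distance +/- 1.96 * dispersion`) are converted through the clock;
#' a lower bound crossing zero is converted as-is by odd extension (so
#' printed-style negative lower age bounds are reproduced), unless
#' `floorAtZero` is set.
#'
#' @param est an [AgeEstimate-class].
#' @param model a [ClockModel-class].
#' @param floorAtZero floor the lower distance bound at 0 before
#'   conversion.
#' @return an [AgeResult-class] (ages in ky).
#' @examples
#' est <- new("AgeEstimate", clade = "W", method = "rho", n = 223L,
#'            distance = 6.8, dispersion = 0.8)
#' ageWithCI(est, correctedClock())
#' @export
ageWithCI <- function(est, model, floorAtZero = FALSE) {
  d <- est@distance
  s <- est@dispersion
  age <- clockConvert(model, d)
  if (is.na(s)) {
    lo <- hi <- NA_real_
  } else {
    dlo <- d - 1.96 * s
    if (floorAtZero) dlo <- max(dlo, 0)
    lo <- clockConvert(model, dlo, allowNegative = TRUE)
    hi <- clockConvert(model, d + 1.96 * s, allowNegative = TRUE)
  }
  new("AgeResult", clade = est@clade, method = est@method, n = est@n,
      distance = d, dispersion = s, ageKy = age, ciLowKy = lo, ciHighKy = hi)
}

#' Age table for the supported subclades of a tree
#'
#' Mirrors the usual published layout: per clade, the sample count, the
#' ML divergence with standard error, age and 95% CI, and the rho
#' distance with heuristic sigma, age and 95% CI (ages in ky, rounded to
#' 0.1).
#'
#' @param tree a [CladePhylogeny-class].
#' @param model a [ClockModel-class].
#' @param nodes nodes to date; default: root plus every subclade from
#'   [detectSubclades()].
#' @param minTips passed to [detectSubclades()].
#' @return data.frame.
#' @export
cladeAgeTable <- function(tree, model, nodes = NULL, minTips = 2L) {
  if (is.null(nodes))
    nodes <- unique(c(1L, detectSubclades(tree, minTips)$node))
  rows <- lapply(nodes, function(nd) {
    lab <- tree@labels[nd]
    lab <- if (is.na(lab)) paste0("node", nd) else lab
    ml <- ageWithCI(mlDivergence(tree, nd, lab), model)
    rh <- ageWithCI(rhoSigma(tree, nd, lab), model)
    data.frame(clade = lab, n = ml@n,
               ml = round(ml@distance, 2), ml_se = round(ml@dispersion, 2),
               ml_age_ky = round(ml@ageKy, 1),
               ml_ci = sprintf("{%.1f; %.1f}", ml@ciLowKy, ml@ciHighKy),
               rho = round(rh@distance, 2), sigma = round(rh@dispersion, 2),
               rho_age_ky = round(rh@ageKy, 1),
               rho_ci = sprintf("{%.1f; %.1f}", rh@ciLowKy, rh@ciHighKy),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
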