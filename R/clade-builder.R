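# Greedy maximum-parsimony construction of haplotype trees.

# A "change" relative to the current ancestral state is a gain (the sample
# carries an event absent from the ancestor, or a different derived state
# at an occupied position) or a loss (an ancestral event absent from the
# sample; rendered as a back mutation "<token>@").
.pendingChanges <- function(tokens, ancestor) {
  av <- if (length(ancestor)) parseVariant(ancestor) else NULL
  gv <- if (length(tokens)) parseVariant(tokens) else NULL
  akey <- if (is.null(av)) character() else .posKey(av)
  gkey <- if (is.null(gv)) character() else .posKey(gv)
  amap <- setNames(if (is.null(av)) character() else av$token, akey)
  gmap <- setNames(if (is.null(gv)) character() else gv$token, gkey)
  keys <- union(akey, gkey)
  out <- list()
  for (k in keys) {
    a <- amap[k]; g <- gmap[k]
    if (!is.na(a) && !is.na(g) && a == g) next
    if (is.na(a)) out[[paste0("+", g)]] <- list(kind = "gain", token = unname(g))
    else if (is.na(g)) out[[paste0("-", a)]] <- list(kind = "loss", token = unname(a))
    else out[[paste0("+", g)]] <- list(kind = "gain", token = unname(g))
  }
  out
}

.applyChange <- function(state, change) {
  v <- parseVariant(change$token)
  k <- .posKey(v)
  if (change$kind == "loss") state[[k]] <- NULL else state[[k]] <- change$token
  state
}

.renderChange <- function(change) {
  if (change$kind == "gain") return(change$token)
  if (endsWith(change$token, "@")) sub("@$", "", change$token)
  else paste0(change$token, "@")
}

#' Build a rooted maximum-parsimony haplotype tree
#'
#' Greedy agglomerative construction: identical masked haplotypes are
#' merged, changes shared by all haplotypes of the current group move onto
#' the stem edge, and the remaining haplotypes are repeatedly split on the
#' unexplained change shared by the most haplotypes.  Candidate splits are
#' ordered by carrier count, then site-stability weight (hypermutable
#' sites are less trusted), then gains before reversions, then lower
#' position, so the construction is deterministic.  Reversions appear only
#' where they shorten the tree (a shared loss explains several haplotypes
#' with one event).  On homoplasy-free input the construction is a perfect
#' phylogeny and attains the optimal parsimony score (total edge mutations
#' equal to the number of distinct variants).
#'
#' Samples whose haplotype equals an internal ancestral state attach
#' directly to that node (paraphyletic lineages).
#'
#' @param profiles list of [VariantProfile-class] with one shared
#'   reference and unique sample ids.
#' @param mask a [SiteMask-class] applied before tree building.
#' @param weights site-stability weights, see [hotspotWeights()].
#' @return a [CladePhylogeny-class].  Replaying the edge mutations from
#'   the root to a sample's node reproduces the sample's masked profile.
#' @examples
#' ps <- list(variantProfile("s1", c("100", "200", "300")),
#'            variantProfile("s2", c("100", "200", "400")))
#' buildCladeTree(ps)
#' @export
buildCladeTree <- function(profiles, mask = defaultSiteMask(),
                           weights = hotspotWeights()) {
  if (length(profiles) == 0L) stop("need at least one profile")
  ids <- vapply(profiles, sampleID, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refs <- unique(vapply(profiles, referenceName, character(1L)))
  if (length(refs) != 1L)
    stop("profiles are relative to different references: ",
         paste(refs, collapse = ", "))
  toks <- lapply(profiles, function(p) .maskTokens(p@tokens, mask))
  if (any(vapply(toks, function(t) any(endsWith(t, "@")), logical(1L))))
    stop("profiles for tree building describe states relative to the ",
         "reference; back-mutation events (\"@\") are produced by the ",
         "builder, not consumed")

  # merge identical haplotypes; deterministic group order
  key <- vapply(toks, function(t) paste(sort(t), collapse = " "), character(1L))
  groups <- lapply(split(seq_along(profiles), key), function(ix)
    list(tokens = toks[[ix[1L]]], samples = ids[ix]))
  groups <- groups[order(names(groups))]

  env <- new.env()
  env$parent <- NA_integer_
  env$edge <- list(character())
  env$samples <- list(character())
  newNode <- function(parentId, edgeTokens) {
    env$parent <- c(env$parent, parentId)
    env$edge <- c(env$edge, list(edgeTokens))
    env$samples <- c(env$samples, list(character()))
    length(env$parent)
  }

  changeOrder <- function(chs, counts) {
    pos <- vapply(chs, function(c) parseVariant(sub("@$", "", c$token))$position,
                  integer(1L))
    w <- .siteWeight(pos, weights)
    gain <- vapply(chs, function(c) c$kind == "gain", logical(1L))
    order(-counts, -w, !gain, pos)
  }

  makeChild <- function(parentId, grps, ancestor) {
    pend <- lapply(grps, function(g) .pendingChanges(g$tokens, ancestor))
    stemIds <- Reduce(intersect, lapply(pend, names))
    state <- ancestor
    stem <- character()
    for (cid in stemIds) {
      ch <- pend[[1L]][[cid]]
      stem <- c(stem, .renderChange(ch))
      state <- .applyChange(state, ch)
    }
    id <- newNode(parentId, stem)
    pend <- lapply(grps, function(g) .pendingChanges(g$tokens, state))
    settled <- lengths(pend) == 0L
    for (g in grps[settled])
      env$samples[[id]] <- c(env$samples[[id]], g$samples)
    active <- grps[!settled]
    pend <- pend[!settled]
    repeat {
      if (length(active) < 2L) break
      allIds <- unlist(lapply(pend, names), use.names = FALSE)
      cnt <- table(allIds)
      shared <- names(cnt)[cnt >= 2L]
      if (length(shared) == 0L) break
      chs <- lapply(shared, function(cid) {
        for (p in pend) if (cid %in% names(p)) return(p[[cid]])
      })
      bestIx <- changeOrder(chs, as.numeric(cnt[shared]))[1L]
      bestId <- shared[bestIx]
      carry <- vapply(pend, function(p) bestId %in% names(p), logical(1L))
      makeChild(id, active[carry], state)
      active <- active[!carry]
      pend <- pend[!carry]
    }
    for (g in active) makeChild(id, list(g), state)
    id
  }

  # root = reference state; absorb changes shared by every haplotype into
  # a basal edge via the ordinary recursion (the root itself stays clean)
  rootId <- 1L
  pend <- lapply(groups, function(g) .pendingChanges(g$tokens, list()))
  settled <- lengths(pend) == 0L
  for (g in groups[settled])
    env$samples[[rootId]] <- c(env$samples[[rootId]], g$samples)
  active <- groups[!settled]
  pend <- pend[!settled]
  repeat {
    if (length(active) == 0L) break
    if (length(active) == 1L) { makeChild(rootId, active, list()); break }
    allIds <- unlist(lapply(pend, names), use.names = FALSE)
    cnt <- table(allIds)
    ord <- names(cnt)[cnt >= 2L]
    if (length(ord) == 0L) {
      for (g in active) makeChild(rootId, list(g), list())
      break
    }
    chs <- lapply(ord, function(cid) {
      for (p in pend) if (cid %in% names(p)) return(p[[cid]])
    })
    bestIx <- changeOrder(chs, as.numeric(cnt[ord]))[1L]
    bestId <- ord[bestIx]
    carry <- vapply(pend, function(p) bestId %in% names(p), logical(1L))
    if (all(carry)) {
      makeChild(rootId, active, list())
      break
    }
    makeChild(rootId, active[carry], list())
    active <- active[!carry]
    pend <- pend[!carry]
  }

  new("CladePhylogeny", parent = env$parent, edgeTokens = env$edge,
      samples = env$samples,
      labels = rep(NA_character_, length(env$parent)), reference = refs)
}

.childrenList <- function(tree) {
  n <- length(tree@parent)
  ch <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    p <- tree@parent[i]
    ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

.subtreeNodes <- function(tree, node) {
  ch <- .childrenList(tree)
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(stack, ch[[v]])
  }
  sort(out)
}

.samplesBelowCount <- function(tree) {
  n <- length(tree@parent)
  cnt <- lengths(tree@samples)
  for (i in rev(seq_len(n)[-1L])) cnt[tree@parent[i]] <- cnt[tree@parent[i]] + cnt[i]
  cnt
}

# Apply an edge-event token to a state map: "...@" removes the event at
# that position, anything else sets it.
.applyEventTokens <- function(state, tokens) {
  for (tok in tokens) {
    if (endsWith(tok, "@")) {
      v <- parseVariant(tok)
      state[[.posKey(v)]] <- NULL
    } else {
      v <- parseVariant(tok)
      state[[.posKey(v)]] <- tok
    }
  }
  state
}

#' Replay edge mutations from the root to every sample
#'
#' @param tree a [CladePhylogeny-class].
#' @return named list: for each sample id, the token set obtained by
#'   applying the edge mutations on its root path.  For trees from
#'   [buildCladeTree()] this equals the sample's masked input profile.
#' @export
replayProfiles <- function(tree) {
  n <- length(tree@parent)
  states <- vector("list", n)
  states[[1L]] <- list()
  for (i in seq_len(n)[-1L])
    states[[i]] <- .applyEventTokens(states[[tree@parent[i]]],
                                     tree@edgeTokens[[i]])
  out <- list()
  for (i in seq_len(n))
    for (s in tree@samples[[i]])
      out[[s]] <- .stateTokens(states[[i]])
  out
}

#' Total number of edge mutations (parsimony score)
#'
#' @param tree a [CladePhylogeny-class].
#' @return integer.
#' @export
parsimonyScore <- function(tree) sum(lengths(tree@edgeTokens))

#' Detect supported subclades
#'
#' Internal nodes with at least `minTips` descendant samples and at least
#' one defining edge mutation, ordered by descendant count (decreasing).
#'
#' @param tree a [CladePhylogeny-class].
#' @param minTips minimum number of descendant samples (>= 2).
#' @return data.frame with columns node, nTips, mutations
#'   (comma-collapsed defining tokens).
#' @export
detectSubclades <- function(tree, minTips = 2L) {
  if (minTips < 2L) stop("minTips must be >= 2")
  below <- .samplesBelowCount(tree)
  keep <- which(below >= minTips & lengths(tree@edgeTokens) >= 1L)
  keep <- keep[order(-below[keep], keep)]
  data.frame(node = keep, nTips = below[keep],
             mutations = vapply(tree@edgeTokens[keep], paste,
                                character(1L), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Report recurrent and reverting positions
#'
#' Every position whose events occur on two or more distinct edges
#' (reversions included) is homoplasic on the tree and is reported with
#' its occurrence count.
#'
#' @param tree a [CladePhylogeny-class].
#' @return data.frame with columns position, occurrences (>= 2), ordered
#'   by occurrences (decreasing) then position.
#' @export
homoplasyScan <- function(tree) {
  perEdge <- lapply(tree@edgeTokens, function(toks) {
    if (length(toks) == 0L) return(integer())
    unique(parseVariant(sub("@$", "", toks))$position)
  })
  cnt <- table(unlist(perEdge, use.names = FALSE))
  cnt <- cnt[cnt >= 2L]
  out <- data.frame(position = as.integer(names(cnt)),
                    occurrences = as.integer(cnt))
  out[order(-out$occurrences, out$position), , drop = FALSE]
}

#' Write a clade tree as annotated Newick
#'
#' Samples become tips (zero-length pendant branches when they sit on
#' internal nodes); edge mutations are attached as comment blocks
#' (`[&mutations=...]`), branch lengths are mutation counts.
#'
#' @param tree a [CladePhylogeny-class].
#' @param file output path; when `""` the string is returned invisibly
#'   without writing.
#' @return the Newick string, invisibly.
#' @export
writeNewick <- function(tree, file = "") {
  ch <- .childrenList(tree)
  fmt <- function(node) {
    kids <- character()
    for (v in ch[[node]]) kids <- c(kids, fmt(v))
    for (s in tree@samples[[node]])
      kids <- c(kids, sprintf("%s:0", gsub("[,();: ]", "_", s)))
    toks <- tree@edgeTokens[[node]]
    ann <- if (length(toks))
      sprintf("[&mutations=%s]", paste(toks, collapse = "|")) else ""
    body <- if (length(kids)) sprintf("(%s)", paste(kids, collapse = ",")) else ""
    if (node == 1L) paste0(body, "root;")
    else sprintf("%s%s:%d", body, ann, length(toks))
  }
  nwk <- fmt(1L)
  if (nzchar(file)) writeLines(nwk, file)
  invisible(nwk)
}

#' Tabular edge list of a clade tree
#'
#' @param tree a [CladePhylogeny-class].
#' @return data.frame (parent, child, mutations, samples).
#' @export
edgeTable <- function(tree) {
  n <- length(tree@parent)
  data.frame(
    parent = tree@parent,
    child = seq_len(n),
    mutations = vapply(tree@edgeTokens, paste, character(1L), collapse = ","),
    samples = vapply(tree@samples, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)[-1L, ]
}
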