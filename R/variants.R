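# Variant nomenclature: parsing, rendering, profiles, masks, distances.

.TOKEN_RE <- "^([0-9]+)(?:\\.([0-9]+))?([ACGTacgt]|[dD])?(@)?$"

#' Parse mtDNA variant tokens
#'
#' Understands the positional nomenclature used throughout the mtDNA
#' literature: a bare position is a transition ("16292"), a position with a
#' base letter a transversion to that base ("8616T"), "d" marks a deletion
#' ("249d"), ".k" plus a base an insertion ("309.1C"), and a trailing "@" a
#' back mutation toward the ancestral state ("195@").
#'
#' @param tokens character vector of tokens.
#' @return data.frame with columns `token` (canonical rendering),
#'   `position`, `insert_index` (NA unless an insertion), `var_class`
#'   (transition, transversion, insertion, deletion, back_mutation),
#'   `derived_base` (NA for plain transitions) and `back_mutation`.
#'   Parsing the canonical rendering reproduces the same rows
#'   (parse-render round trip).
#' @examples
#' parseVariant(c("8616T", "195@", "16292", "309.1C", "249d"))
#' @export
parseVariant <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L)
    return(data.frame(token = character(), position = integer(),
                      insert_index = integer(), var_class = character(),
                      derived_base = character(), back_mutation = logical(),
                      stringsAsFactors = FALSE))
  bad <- function(tok, why)
    stop(sprintf("malformed variant token '%s': %s", tok, why), call. = FALSE)
  nomatch <- !grepl(.TOKEN_RE, tokens)
  if (any(nomatch))
    bad(tokens[nomatch][1L], "does not match the nomenclature grammar")
  pos <- as.integer(sub(.TOKEN_RE, "\\1", tokens))
  insS <- sub(.TOKEN_RE, "\\2", tokens)
  ins <- ifelse(nzchar(insS), suppressWarnings(as.integer(insS)), NA_integer_)
  letter <- toupper(sub(.TOKEN_RE, "\\3", tokens))
  back <- sub(.TOKEN_RE, "\\4", tokens) == "@"

  off <- is.na(pos) | pos < 1L | pos > .MT_LENGTH
  if (any(off))
    bad(tokens[off][1L], sprintf("position outside 1..%d", .MT_LENGTH))
  isIns <- !is.na(ins)
  if (any(isIns & ins < 1L))
    bad(tokens[isIns & ins < 1L][1L], "insertion index must be >= 1")
  if (any(isIns & (letter == "" | letter == "D")))
    bad(tokens[isIns & (letter == "" | letter == "D")][1L],
        "insertion requires an inserted base")
  if (any(isIns & back))
    bad(tokens[isIns & back][1L], "back mutation not defined for insertions")
  isDel <- !isIns & letter == "D"
  if (any(isDel & back))
    bad(tokens[isDel & back][1L], "back mutation not defined for deletions")

  cls <- ifelse(isIns, "insertion",
         ifelse(isDel, "deletion",
         ifelse(back, "back_mutation",
         ifelse(letter != "", "transversion", "transition"))))
  base <- ifelse(isIns | (!isDel & letter != ""), letter, NA_character_)
  canonical <- paste0(pos, ifelse(isIns, paste0(".", ins), ""),
                      ifelse(isDel, "d", ifelse(is.na(base), "", base)),
                      ifelse(back, "@", ""))
  data.frame(token = canonical, position = pos, insert_index = ins,
             var_class = cls, derived_base = base, back_mutation = back,
             stringsAsFactors = FALSE)
}

#' Render parsed variants back to canonical tokens
#'
#' @param variants data.frame as returned by [parseVariant()].
#' @return character vector of canonical tokens.
#' @export
renderVariant <- function(variants) {
  paste0(variants$position,
         ifelse(is.na(variants$insert_index), "",
                paste0(".", variants$insert_index)),
         ifelse(variants$var_class == "deletion", "d",
                ifelse(is.na(variants$derived_base), "", variants$derived_base)),
         ifelse(variants$back_mutation, "@", ""))
}

.canonicalTokens <- function(tokens) {
  v <- parseVariant(tokens)
  v <- v[!duplicated(v$token), , drop = FALSE]
  v$token[order(v$position, ifelse(is.na(v$insert_index), 0L, v$insert_index))]
}

.posKey <- function(v) {
  paste(v$position, ifelse(is.na(v$insert_index), 0L, v$insert_index))
}

#' Construct a VariantProfile
#'
#' @param sampleID sample identifier.
#' @param tokens variant tokens (any order; canonicalised and sorted).
#' @param reference name of the reference the tokens are relative to.
#' @param region covered region: "full_genome", "HVS-I" or
#'   "control_region".
#' @return a [VariantProfile-class].
#' @examples
#' variantProfile("anc1", c("16192", "16223", "16292", "16325"),
#'                region = "HVS-I")
#' @export
variantProfile <- function(sampleID, tokens = character(),
                           reference = "rCRS", region = "full_genome") {
  new("VariantProfile", sampleID = as.character(sampleID),
      reference = reference, tokens = .canonicalTokens(tokens),
      region = match.arg(region, .REGIONS))
}

#' Site masks for distance and dating computations
#'
#' `defaultSiteMask()` excludes 16182C, 16183C and 16519, the unstable
#' sites conventionally dropped from whole-mtDNA distance and age
#' computations.  Masking applies to distances and dating only; haplogroup
#' motifs are matched unmasked.
#'
#' @param tokens mask tokens; a bare position masks every event there.
#' @return a [SiteMask-class].
#' @export
siteMask <- function(tokens = character()) {
  new("SiteMask", tokens = as.character(tokens))
}

#' @rdname siteMask
#' @export
defaultSiteMask <- function() siteMask(c("16182C", "16183C", "16519"))

#' @rdname siteMask
#' @export
emptySiteMask <- function() siteMask(character())

.maskTokens <- function(tokens, mask) {
  if (length(tokens) == 0L || length(mask@tokens) == 0L) return(tokens)
  v <- parseVariant(tokens)
  mk <- parseVariant(mask@tokens)
  hit <- vapply(seq_len(nrow(v)), function(i) {
    any(mk$position == v$position[i] &
          (is.na(mk$derived_base) |
             (!is.na(v$derived_base[i]) & mk$derived_base == v$derived_base[i])))
  }, logical(1L))
  tokens[!hit]
}

#' Remove masked sites from a profile
#'
#' Returns a copy of the profile without the variants whose identity is in
#' the mask; the input is unchanged.
#'
#' @param x a [VariantProfile-class] (or a character vector of tokens).
#' @param mask a [SiteMask-class].
#' @return same class as `x`.
#' @examples
#' p <- variantProfile("s", c("16519", "10034"))
#' variantTokens(applyMask(p))
#' @export
setMethod("applyMask", "VariantProfile", function(x, mask = defaultSiteMask()) {
  initialize(x, tokens = .maskTokens(x@tokens, mask))
})

#' @rdname applyMask
#' @export
setMethod("applyMask", "character", function(x, mask = defaultSiteMask()) {
  .maskTokens(x, mask)
})

#' Masked symmetric-difference distance between two profiles
#'
#' Counts the variants present in exactly one of the two masked profiles.
#' This is a metric on masked profiles and is the pairwise distance used by
#' the tree builder.
#'
#' @param a,b [VariantProfile-class] objects with the same reference.
#' @param mask a [SiteMask-class].
#' @return integer distance.
#' @export
profileDistance <- function(a, b, mask = defaultSiteMask()) {
  if (!identical(a@reference, b@reference))
    stop("profiles are relative to different references: ",
         a@reference, " vs ", b@reference)
  ta <- .maskTokens(a@tokens, mask)
  tb <- .maskTokens(b@tokens, mask)
  length(setdiff(ta, tb)) + length(setdiff(tb, ta))
}

# Shift gap runs leftward through homopolymer tracts so indel placement is
# deterministic regardless of how the aligner placed the gap.
.leftAlignGaps <- function(x, y) {
  n <- length(x)
  i <- 2L
  while (i <= n) {
    if (x[i] == "-" && x[i - 1L] != "-") {
      j <- i
      while (j < n && x[j + 1L] == "-") j <- j + 1L
      while (i > 1L && x[i - 1L] != "-" && y[i - 1L] != "-" &&
             y[i - 1L] == y[j] && x[i - 1L] == y[j]) {
        x[j] <- x[i - 1L]; x[i - 1L] <- "-"
        i <- i - 1L; j <- j - 1L
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  x
}

.TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Call a variant profile from an aligned sequence pair
#'
#' Compares an aligned sample sequence with the aligned reference column by
#' column and reports every difference as a variant token in reference
#' coordinates: transitions as bare positions, transversions with the
#' derived base, deletions as "<pos>d" and insertions as
#' "<pos>.<k><base>".  Gap runs are left-aligned through homopolymer
#' tracts before calling so indel placement is deterministic.  Ambiguity
#' codes (anything outside A, C, G, T and "-") are rejected.
#'
#' @param seq sample sequence (character string or `DNAString`-like).
#' @param ref reference sequence of the same alignment length.
#' @param sampleID sample identifier for the resulting profile.
#' @param reference name recorded as the profile's reference.
#' @return a [VariantProfile-class] with region "full_genome".
#' @examples
#' profileFromSequence("ACGTA", "ACGGA", sampleID = "s1", reference = "toy")
#' @export
profileFromSequence <- function(seq, ref, sampleID = "sample",
                                reference = "rCRS") {
  s <- toupper(as.character(seq))
  r <- toupper(as.character(ref))
  if (nchar(s) != nchar(r))
    stop("sequence and reference have different alignment lengths (",
         nchar(s), " vs ", nchar(r), ")")
  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  rv <- strsplit(r, "", fixed = TRUE)[[1L]]
  ok <- c("A", "C", "G", "T", "-")
  badc <- unique(c(sv[!sv %in% ok], rv[!rv %in% ok]))
  if (length(badc))
    stop("non-IUPAC or ambiguity characters rejected: ",
         paste(badc, collapse = ", "))
  if (any(sv == "-" & rv == "-")) {
    keep <- !(sv == "-" & rv == "-")
    sv <- sv[keep]; rv <- rv[keep]
  }
  if (any(sv == "-")) sv <- .leftAlignGaps(sv, rv)
  if (any(rv == "-")) rv <- .leftAlignGaps(rv, sv)

  tokens <- character()
  if (!any(sv == "-") && !any(rv == "-")) {
    # fast path: ungapped alignment
    d <- which(sv != rv)
    if (length(d)) {
      ts <- .TRANSITION_PARTNER[rv[d]] == sv[d]
      tokens <- ifelse(ts, as.character(d), paste0(d, sv[d]))
    }
  } else {
    refpos <- 0L
    insIdx <- 0L
    for (i in seq_along(rv)) {
      if (rv[i] != "-") { refpos <- refpos + 1L; insIdx <- 0L }
      if (sv[i] == rv[i]) next
      if (rv[i] == "-") {
        insIdx <- insIdx + 1L
        if (refpos == 0L)
          stop("insertion before the first reference position")
        tokens <- c(tokens, paste0(refpos, ".", insIdx, sv[i]))
      } else if (sv[i] == "-") {
        tokens <- c(tokens, paste0(refpos, "d"))
      } else {
        ts <- .TRANSITION_PARTNER[[rv[i]]] == sv[i]
        tokens <- c(tokens, if (ts) as.character(refpos)
                    else paste0(refpos, sv[i]))
      }
    }
  }
  variantProfile(sampleID, tokens, reference = reference)
}

#' Call profiles for every record of an aligned multi-FASTA
#'
#' @param file path to an aligned multi-FASTA.
#' @param refName name of the record to use as the reference; by default
#'   the first record.
#' @param reference reference label stored in the profiles (defaults to
#'   `refName`).
#' @return list of [VariantProfile-class], one per non-reference record.
#' @export
profilesFromFasta <- function(file, refName = NULL, reference = refName) {
  seqs <- Biostrings::readDNAStringSet(file)
  if (length(seqs) < 2L) stop("need a reference and at least one sample")
  if (is.null(refName)) refName <- names(seqs)[1L]
  if (!refName %in% names(seqs)) stop("reference record not found: ", refName)
  if (is.null(reference)) reference <- refName
  ref <- as.character(seqs[[refName]])
  others <- setdiff(names(seqs), refName)
  lapply(others, function(nm)
    profileFromSequence(as.character(seqs[[nm]]), ref, sampleID = nm,
                        reference = reference))
}

#' Read and write variant-profile tables
#'
#' The plain-text format has one sample per line:
#' `sample_id<TAB>space-separated tokens` (an empty token field means no
#' variants).
#'
#' @param file path.
#' @param reference,region recorded in each profile.
#' @return `readProfiles`: list of [VariantProfile-class].
#' @export
readProfiles <- function(file, reference = "rCRS", region = "full_genome") {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    toks <- if (length(parts) > 1L && nzchar(trimws(parts[2L])))
      strsplit(trimws(parts[2L]), "[ ,]+")[[1L]] else character()
    variantProfile(parts[1L], toks, reference = reference, region = region)
  })
}

#' @rdname readProfiles
#' @param profiles list of [VariantProfile-class].
#' @export
writeProfiles <- function(profiles, file) {
  lines <- vapply(profiles, function(p)
    paste(p@sampleID, paste(p@tokens, collapse = " "), sep = "\t"),
    character(1L))
  writeLines(lines, file)
}
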