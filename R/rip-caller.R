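#' Call RIP mutations in a spore contig
#'
#' Compares a sequenced spore contig to the expected cassette sequence and
#' classifies every mismatch: expected C observed T is a `"CT"` call,
#' expected G observed A a `"GA"` call, and any other mismatch `"other"`
#' (reported but excluded from RIP statistics). RIP introduces substitutions
#' only, so the default `positional` mode compares site by site and requires
#' equal lengths. `gapped` mode first computes a global pairwise alignment
#' (match 1, mismatch -2, gap opening -6, gap extension -1) for contigs with
#' sequencing indels; gap columns are excluded from the counts and their
#' number is logged, and an alignment with more than 20% gap columns is
#' rejected as a likely wrong construct assignment. Positions are 1-based in
#' the expected sequence.
#'
#' @param expected expected cassette sequence (DNAString or character).
#' @param spore observed spore contig (DNAString or character).
#' @param mode `"positional"` (default) or `"gapped"`.
#' @param sporeId character identifier stored in the result.
#' @return A [MutationCallSet-class].
#' @examples
#' calls <- callMutations("CCGG", "TCGA", sporeId = "SIMA1_1")
#' c(nCT(calls), nGA(calls), nOther(calls))
#' @export
callMutations <- function(expected, spore, mode = c("positional", "gapped"),
                          sporeId = "spore") {
  mode <- match.arg(mode)
  expc <- .asDnaChars(expected, "expected")
  sprc <- .asDnaChars(spore, "spore")

  if (mode == "positional") {
    if (length(expc) != length(sprc)) {
      stop("positional mode requires equal lengths (expected: ",
           length(expc), " bp, spore: ", length(sprc),
           " bp); use mode = \"gapped\"", call. = FALSE)
    }
    epos <- seq_along(expc)
    e <- expc; s <- sprc
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    aln <- Biostrings::pairwiseAlignment(
      .charsToDNAString(expc), .charsToDNAString(sprc),
      type = "global", substitutionMatrix = sm,
      gapOpening = 6, gapExtension = 1)
    e <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gap <- e == "-" | s == "-"
    if (mean(gap) > 0.20) {
      stop("alignment has ", round(100 * mean(gap), 1),
           "% gap columns (> 20%); spore likely assigned to the wrong ",
           "construct", call. = FALSE)
    }
    if (any(gap)) {
      message(sum(gap), " gap column(s) excluded from mutation counts for ",
              sporeId)
    }
    epos <- cumsum(e != "-")  # 1-based position in the expected sequence
    keep <- !gap
    e <- e[keep]; s <- s[keep]; epos <- epos[keep]
  }

  mism <- which(e != s)
  cls <- character(length(mism))
  cls[] <- "other"
  cls[e[mism] == "C" & s[mism] == "T"] <- "CT"
  cls[e[mism] == "G" & s[mism] == "A"] <- "GA"
  new("MutationCallSet",
      sporeId = sporeId,
      positions = as.integer(epos[mism]),
      classes = cls,
      refLength = length(expc))
}

#' @rdname accessors
#' @export
setMethod("sporeId", "MutationCallSet", function(x) x@sporeId)

#' @rdname accessors
#' @export
setMethod("mutationPositions", "MutationCallSet", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("mutationClasses", "MutationCallSet", function(x) x@classes)

#' @rdname accessors
#' @export
setMethod("nCT", "MutationCallSet", function(x) sum(x@classes == "CT"))

#' @rdname accessors
#' @export
setMethod("nGA", "MutationCallSet", function(x) sum(x@classes == "GA"))

#' @rdname accessors
#' @export
setMethod("nOther", "MutationCallSet", function(x) sum(x@classes == "other"))

# Per-spore RIP totals (CT + GA), optionally restricted to a 1-based
# inclusive region c(start, end).
.ripTotals <- function(calls, region = NULL) {
  vapply(calls, function(cs) {
    keep <- cs@classes %in% c("CT", "GA")
    if (!is.null(region)) {
      keep <- keep & cs@positions >= region[1] & cs@positions <= region[2]
    }
    sum(keep)
  }, numeric(1))
}

#' Mean RIP mutations per spore
#'
#' The study's primary quantitative measure of RIP: the arithmetic mean of
#' per-spore mutation totals (C-to-T plus G-to-A calls), with the standard
#' error of the mean (sample standard deviation, n - 1 denominator, divided
#' by sqrt(n); reported as 0 when n = 1). A region restricts the totals to
#' calls within a 1-based inclusive interval, as when quantifying only the
#' 500-bp reference region of a compound construct.
#'
#' @param calls list of [MutationCallSet-class] objects (one per spore).
#' @param region optional `c(start, end)`, 1-based inclusive.
#' @return `list(mean, sem, n)`.
#' @examples
#' a <- callMutations("CCGG", "TTGG"); b <- callMutations("CCGG", "TTGA")
#' meanMutations(list(a, b))
#' @export
meanMutations <- function(calls, region = NULL) {
  if (length(calls) == 0) stop("empty call list", call. = FALSE)
  totals <- .ripTotals(calls, region)
  n <- length(totals)
  list(mean = mean(totals),
       sem = if (n == 1) 0 else stats::sd(totals) / sqrt(n),
       n = n)
}

#' Per-site mutation profile across spores
#'
#' For each position of the expected sequence, counts the spores carrying a
#' RIP mutation (C-to-T or G-to-A) there. Percent incidence
#' (`sitePercent()`) expresses the count as percent of all spores profiled,
#' the scale on which construct mutation profiles are plotted.
#'
#' @param calls list of [MutationCallSet-class] objects.
#' @param length integer sequence length; defaults to the maximum
#'   `refLength` among the calls.
#' @param construct character construct label.
#' @return A [SiteProfile-class].
#' @export
siteProfile <- function(calls, length = NULL, construct = "") {
  if (base::length(calls) == 0) stop("empty call list", call. = FALSE)
  if (is.null(length)) {
    length <- max(vapply(calls, function(cs) cs@refLength, integer(1)))
  }
  length <- as.integer(length)
  counts <- integer(length)
  for (cs in calls) {
    pos <- cs@positions[cs@classes %in% c("CT", "GA")]
    if (base::length(pos) && max(pos) > length) {
      stop("call position ", max(pos), " exceeds profile length ", length,
           call. = FALSE)
    }
    # a spore contributes at most one count per site
    counts[unique(pos)] <- counts[unique(pos)] + 1L
  }
  new("SiteProfile", construct = construct, siteCounts = counts,
      nSpores = base::length(calls))
}

#' @rdname accessors
#' @export
setMethod("siteCounts", "SiteProfile", function(x) x@siteCounts)

#' @rdname accessors
#' @export
setMethod("sitePercent", "SiteProfile", function(x)
  100 * x@siteCounts / x@nSpores)

#' @rdname accessors
#' @export
setMethod("nSpores", "SiteProfile", function(x) x@nSpores)
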