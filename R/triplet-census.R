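#' Canonical form of a DNA triplet
#'
#' Collapses a 3-mer with its reverse complement into one canonical class,
#' defined as the lexicographically smaller of the two words. No 3-mer equals
#' its own reverse complement (the middle base would have to be
#' self-complementary), so the 64 triplets fall into exactly 32 classes. The
#' function is vectorized and idempotent.
#'
#' @param t character vector of 3-mers over A/C/G/T.
#' @return Character vector of canonical 3-mers.
#' @examples
#' canonicalTriplet(c("GTC", "AAA"))  # "GAC", "AAA"
#' @export
canonicalTriplet <- function(t) {
  if (!is.character(t)) stop("t must be a character vector", call. = FALSE)
  if (any(nchar(t) != 3)) stop("every element must be a 3-mer", call. = FALSE)
  up <- toupper(t)
  if (!all(strsplit(paste(up, collapse = ""), "")[[1]] %in% DNA_BASES)) {
    stop("triplets must contain only A, C, G, T", call. = FALSE)
  }
  rc <- vapply(strsplit(up, "", fixed = TRUE), function(ch)
    paste(.reverseComplementChars(ch), collapse = ""), character(1))
  ifelse(up <= rc, up, rc)
}

#' The 32 canonical triplet classes
#'
#' @return Sorted character vector of the 32 canonical 3-mers.
#' @export
allCanonicalTriplets <- function() {
  words <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                             stringsAsFactors = FALSE),
                 1, paste, collapse = "")
  sort(unique(canonicalTriplet(words)))
}

#' Census the triplets contained in homologous units
#'
#' Enumerates the 3-bp words contained in the homologous units of a cassette
#' and counts them under their canonical (strand-collapsed) names. Units are
#' the maximal homologous runs of the cassette's mask: a run of length
#' l >= 3 contributes its l - 2 overlapping triplets, read from the
#' reference copy; shorter runs contribute nothing. Forward and
#' reverse-complement instances are pooled.
#'
#' @param x a [Cassette-class].
#' @param ... unused.
#' @return A [TripletCensus-class] with all 32 canonical classes (zeros
#'   included).
#' @examples
#' cas <- Cassette("GACTAAAAAAA", "GACTCCGCCGC")
#' tripletCounts(enumerateUnitTriplets(cas))[c("GAC", "ACT")]
#' @export
setMethod("enumerateUnitTriplets", "Cassette", function(x, ...) {
  refc <- strsplit(as.character(x@referenceCopy), "")[[1]]
  runs <- .maskRuns(x@homologyMask)
  counts <- stats::setNames(integer(32), allCanonicalTriplets())
  big <- runs[runs$width >= 3, , drop = FALSE]
  if (nrow(big)) {
    words <- unlist(lapply(seq_len(nrow(big)), function(i) {
      starts <- big$start[i]:(big$end[i] - 2L)
      vapply(starts, function(s) paste(refc[s:(s + 2L)], collapse = ""),
             character(1))
    }))
    tab <- table(canonicalTriplet(words))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  new("TripletCensus", counts = counts,
      unitCount = nrow(runs), unitLengths = as.integer(runs$width))
})

#' @rdname accessors
#' @export
setMethod("tripletCounts", "TripletCensus", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("censusTotal", "TripletCensus", function(x) sum(x@counts))

#' Tabulate a triplet census
#'
#' @param census a [TripletCensus-class].
#' @param dropZeros logical, drop classes with zero count (default `TRUE`).
#' @return `data.frame(triplet, count)` sorted by decreasing count, then
#'   name.
#' @export
censusTable <- function(census, dropZeros = TRUE) {
  stopifnot(is(census, "TripletCensus"))
  df <- data.frame(triplet = names(census@counts),
                   count = unname(census@counts),
                   stringsAsFactors = FALSE)
  if (dropZeros) df <- df[df$count > 0, , drop = FALSE]
  df <- df[order(-df$count, df$triplet), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Reverse-complement a whole cassette
#'
#' Reverse-complements both copies and reverses the mask; the triplet census
#' is invariant under this operation.
#'
#' @param cassette a [Cassette-class].
#' @return The reverse-complemented [Cassette-class].
#' @export
reverseComplementCassette <- function(cassette) {
  stopifnot(is(cassette, "Cassette"))
  new("Cassette",
      referenceCopy = Biostrings::reverseComplement(cassette@referenceCopy),
      testCopy = Biostrings::reverseComplement(cassette@testCopy),
      homologyMask = rev(cassette@homologyMask),
      id = paste0(cassette@id, "_rc"),
      provenance = cassette@provenance)
}
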