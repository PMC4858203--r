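#' Interspersed-homology pattern (XH-YN_Z)
#'
#' Parameterizes a pattern of interspersed DNA homology over a region of
#' `regionLen` base pairs: homologous units of `unitLen` (X) base pairs,
#' separated by `spacerLen` (Y) base pairs of non-homology, the first unit
#' starting at 1-based sequence position `seqPos` (Z). The periodicity of the
#' pattern is X + Y and its canonical name renders as `"XH-YN_Z"` (e.g.
#' X = 4, Y = 7, Z = 1 gives `"4H-7N_1"`).
#'
#' Positions before Z are never homologous. `endPolicy` controls what happens
#' at the right edge of the region: `"truncate"` (the default) clips any unit
#' crossing the region end, while `"extend"` lengthens the final unit by
#' `extendBy` extra positions (still clipped at the region end) — this exists
#' to reproduce construct variants whose last unit was accidentally extended.
#'
#' @slot unitLen integer, homologous unit length X (bp), X >= 0.
#' @slot spacerLen integer, non-homologous spacer length Y (bp), Y >= 0;
#'   X + Y >= 1.
#' @slot seqPos integer, 1-based start of the first homologous unit (Z >= 1).
#' @slot regionLen integer, region length L (bp), L >= 1.
#' @slot endPolicy `"truncate"` or `"extend"`.
#' @slot extendBy integer >= 0, extra positions appended to the final unit
#'   when `endPolicy == "extend"`.
#'
#' @seealso [HomologyPattern()], [homologousPositions()], [generateTest()]
#' @export
setClass("HomologyPattern",
  representation(
    unitLen = "integer",
    spacerLen = "integer",
    seqPos = "integer",
    regionLen = "integer",
    endPolicy = "character",
    extendBy = "integer"
  )
)

setValidity("HomologyPattern", function(object) {
  msgs <- character(0)
  X <- object@unitLen; Y <- object@spacerLen
  Z <- object@seqPos; L <- object@regionLen
  if (length(X) != 1 || is.na(X) || X < 0) msgs <- c(msgs, "unitLen (X) must be a single integer >= 0")
  if (length(Y) != 1 || is.na(Y) || Y < 0) msgs <- c(msgs, "spacerLen (Y) must be a single integer >= 0")
  if (length(X) == 1 && length(Y) == 1 && !is.na(X) && !is.na(Y) && X + Y < 1)
    msgs <- c(msgs, "periodicity X + Y must be >= 1")
  if (length(Z) != 1 || is.na(Z) || Z < 1) msgs <- c(msgs, "seqPos (Z) must be a single integer >= 1")
  if (length(L) != 1 || is.na(L) || L < 1) msgs <- c(msgs, "regionLen (L) must be a single integer >= 1")
  if (!object@endPolicy %in% c("truncate", "extend"))
    msgs <- c(msgs, "endPolicy must be 'truncate' or 'extend'")
  if (length(object@extendBy) != 1 || is.na(object@extendBy) || object@extendBy < 0)
    msgs <- c(msgs, "extendBy must be a single integer >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A realized repeat cassette: reference copy, test copy, homology mask
#'
#' Holds the two aligned copies of a repeat construct — the fixed "left"
#' reference copy and the designed "right" test copy — together with the
#' homology mask over their (equal-length) positions. The mask is the single
#' source of truth for homology: it is `TRUE` exactly where the test base
#' equals the aligned reference base, and `FALSE` exactly where it differs;
#' the class validity enforces this, so a `Cassette` can never carry an
#' inconsistent mask.
#'
#' @slot referenceCopy [Biostrings::DNAString] reference (left) copy.
#' @slot testCopy [Biostrings::DNAString] test (right) copy, same length.
#' @slot homologyMask logical vector over positions, `TRUE` = homologous.
#' @slot id character label for the cassette.
#' @slot provenance list recording how the cassette was built (pattern,
#'   spec, seed, edits).
#'
#' @seealso [Cassette()], [generateTest()], [composeCassette()],
#'   [deleteUnitTriplet()]
#' @export
setClass("Cassette",
  representation(
    referenceCopy = "DNAString",
    testCopy = "DNAString",
    homologyMask = "logical",
    id = "character",
    provenance = "list"
  )
)

setValidity("Cassette", function(object) {
  refc <- strsplit(as.character(object@referenceCopy), "")[[1]]
  tstc <- strsplit(as.character(object@testCopy), "")[[1]]
  if (length(refc) != length(tstc))
    return("reference and test copies differ in length")
  if (length(object@homologyMask) != length(refc))
    return("homology mask length differs from sequence length")
  if (anyNA(object@homologyMask))
    return("homology mask contains NA")
  eq <- refc == tstc
  if (!identical(unname(eq), unname(object@homologyMask)))
    return("homology mask inconsistent with position-wise sequence equality")
  TRUE
})

#' Specification of a full repeat cassette
#'
#' Describes the composition of a complete repeat construct: a reference
#' segment carrying an interspersed-homology pattern (or perfect homology)
#' over its full length, an optional adjacent block of 0-100+ bp on the left
#' or right (itself perfect or patterned), an optional random junction insert
#' between block and region, and an optional interruption replacing part of
#' the block with non-homology.
#'
#' @slot reference [Biostrings::DNAString] reference for the main region;
#'   its length is the region length L.
#' @slot pattern500 a [HomologyPattern-class] for the main region, or the
#'   string `"perfect"`.
#' @slot blockLen integer block length in bp (0 = no block).
#' @slot blockSide `"left"`, `"right"` or `"none"`; `"none"` iff
#'   `blockLen == 0`.
#' @slot blockPattern [HomologyPattern-class] or `"perfect"` for the block.
#' @slot blockReference [Biostrings::DNAString] of length `blockLen`, or
#'   `NULL` to sample one from the seed's child stream.
#' @slot junctionInsertLen integer >= 0, random non-homologous bp inserted at
#'   the block/region junction.
#' @slot interruption integer(0) for none, or `c(start, len)` (1-based within
#'   the block) replaced by non-matching bases in the test copy.
#'
#' @seealso [CassetteSpec()], [composeCassette()]
#' @export
setClass("CassetteSpec",
  representation(
    reference = "DNAString",
    pattern500 = "ANY",
    blockLen = "integer",
    blockSide = "character",
    blockPattern = "ANY",
    blockReference = "ANY",
    junctionInsertLen = "integer",
    interruption = "integer"
  )
)

.validPatternOrPerfect <- function(x, what) {
  if (is(x, "HomologyPattern")) return(character(0))
  if (identical(x, "perfect")) return(character(0))
  paste0(what, " must be a HomologyPattern or the string 'perfect'")
}

setValidity("CassetteSpec", function(object) {
  msgs <- character(0)
  msgs <- c(msgs, .validPatternOrPerfect(object@pattern500, "pattern500"))
  msgs <- c(msgs, .validPatternOrPerfect(object@blockPattern, "blockPattern"))
  if (object@blockLen < 0) msgs <- c(msgs, "blockLen must be >= 0")
  if (!object@blockSide %in% c("left", "right", "none"))
    msgs <- c(msgs, "blockSide must be 'left', 'right' or 'none'")
  if ((object@blockLen == 0) != (object@blockSide == "none"))
    msgs <- c(msgs, "blockLen == 0 if and only if blockSide == 'none'")
  if (object@junctionInsertLen < 0)
    msgs <- c(msgs, "junctionInsertLen must be >= 0")
  if (!length(object@interruption) %in% c(0L, 2L))
    msgs <- c(msgs, "interruption must be integer(0) or c(start, len)")
  if (length(object@interruption) == 2) {
    st <- object@interruption[1]; len <- object@interruption[2]
    if (st < 1 || len < 1 || st + len - 1 > object@blockLen)
      msgs <- c(msgs, "interruption must lie within the block")
  }
  if (!is.null(object@blockReference)) {
    if (!is(object@blockReference, "DNAString"))
      msgs <- c(msgs, "blockReference must be a DNAString or NULL")
    else if (length(object@blockReference) != object@blockLen)
      msgs <- c(msgs, "blockReference length must equal blockLen")
  }
  if (length(msgs)) msgs else TRUE
})

#' Called RIP mutations of one spore contig
#'
#' The substitutions found when comparing one sequenced spore contig to its
#' expected cassette sequence, each classified as `"CT"` (expected C observed
#' T), `"GA"` (expected G observed A) or `"other"` (any other mismatch,
#' excluded from RIP statistics).
#'
#' @slot sporeId character spore identifier (typically
#'   `"{RepeatID}{cross}_{spore}"`).
#' @slot positions integer, 1-based positions in the expected sequence.
#' @slot classes character parallel to `positions`, each `"CT"`, `"GA"` or
#'   `"other"`.
#' @slot refLength integer, length of the expected sequence.
#'
#' @seealso [callMutations()], [meanMutations()], [siteProfile()]
#' @export
setClass("MutationCallSet",
  representation(
    sporeId = "character",
    positions = "integer",
    classes = "character",
    refLength = "integer"
  )
)

setValidity("MutationCallSet", function(object) {
  msgs <- character(0)
  if (length(object@positions) != length(object@classes))
    msgs <- c(msgs, "positions and classes must have equal length")
  if (!all(object@classes %in% c("CT", "GA", "other")))
    msgs <- c(msgs, "classes must be 'CT', 'GA' or 'other'")
  if (length(object@positions) &&
      (any(object@positions < 1) || any(object@positions > object@refLength)))
    msgs <- c(msgs, "positions must lie in [1, refLength]")
  if (length(msgs)) msgs else TRUE
})

#' Per-site mutation profile of one construct
#'
#' For every position of the expected cassette sequence, the number of spores
#' carrying a RIP mutation (C-to-T or G-to-A) there, out of `nSpores` spores
#' sequenced for the construct. Percent incidence is `100 * count / nSpores`.
#'
#' @slot construct character construct label (RepeatID).
#' @slot siteCounts integer vector, one count per position.
#' @slot nSpores integer, number of spores profiled.
#'
#' @seealso [siteProfile()], [profileCorrelation()]
#' @export
setClass("SiteProfile",
  representation(
    construct = "character",
    siteCounts = "integer",
    nSpores = "integer"
  )
)

setValidity("SiteProfile", function(object) {
  msgs <- character(0)
  if (object@nSpores < 1) msgs <- c(msgs, "nSpores must be >= 1")
  if (length(object@siteCounts) &&
      (any(object@siteCounts < 0) || any(object@siteCounts > object@nSpores)))
    msgs <- c(msgs, "siteCounts must lie in [0, nSpores]")
  if (length(msgs)) msgs else TRUE
})

#' Census of canonical triplets in homologous units
#'
#' Counts of the 3-bp words contained in the homologous units of a cassette,
#' with forward and reverse-complement instances of each triplet pooled into
#' one canonical class (the lexicographically smaller of the word and its
#' reverse complement). No 3-mer is its own reverse complement, so there are
#' exactly 32 canonical classes; `counts` always carries all 32, including
#' zeros. Counting is over maximal homologous runs: a run of length l >= 3
#' contributes its l - 2 overlapping triplets (read from the reference copy),
#' runs shorter than 3 contribute nothing.
#'
#' @slot counts named integer vector over the 32 canonical triplets.
#' @slot unitCount integer, number of maximal homologous runs in the mask.
#' @slot unitLengths integer vector of the run lengths.
#'
#' @seealso [enumerateUnitTriplets()], [canonicalTriplet()]
#' @export
setClass("TripletCensus",
  representation(
    counts = "integer",
    unitCount = "integer",
    unitLengths = "integer"
  )
)

setValidity("TripletCensus", function(object) {
  msgs <- character(0)
  if (length(object@counts) != 32 || is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be a named integer vector over the 32 canonical triplets")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  expected <- sum(pmax(object@unitLengths - 2L, 0L))
  if (sum(object@counts) != expected)
    msgs <- c(msgs, "sum of counts must equal sum over runs of (length - 2)")
  if (length(msgs)) msgs else TRUE
})

#' Phenomenological RIP simulation model
#'
#' Parameters of the stochastic spore simulator. Each spore escapes RIP
#' entirely with probability `escapeProb`; otherwise it receives a
#' Poisson(`lambdaMean`) number of mutations, each assigned to the C-to-T
#' class with probability `ctGaRatio` (else G-to-A) and placed without
#' replacement among the class's mutable sites (reference C's for C-to-T,
#' G's for G-to-A) with probabilities proportional to `spatialProfile`. The
#' default spatial profile is a symmetric triangle peaking at the sequence
#' center, emulating the observed concentration of mutations near the middle
#' of compound repeats. `indelRate` (default 0) deletes each position
#' independently after mutagenesis, for exercising gapped calling.
#'
#' @slot lambdaMean numeric >= 0, expected mutations per non-escaping spore.
#' @slot escapeProb numeric in \[0, 1\], fraction of spores with zero RIP.
#' @slot spatialProfile numeric weight per position (empty = default
#'   triangular); negative weights are invalid.
#' @slot ctGaRatio numeric in \[0, 1\], probability a mutation is C-to-T.
#' @slot indelRate numeric in \[0, 1\], per-position deletion probability.
#'
#' @seealso [RipSimModel()], [simulateSpores()], [emulateStudy()]
#' @export
setClass("RipSimModel",
  representation(
    lambdaMean = "numeric",
    escapeProb = "numeric",
    spatialProfile = "numeric",
    ctGaRatio = "numeric",
    indelRate = "numeric"
  )
)

setValidity("RipSimModel", function(object) {
  msgs <- character(0)
  if (object@lambdaMean < 0) msgs <- c(msgs, "lambdaMean must be >= 0")
  for (nm in c("escapeProb", "ctGaRatio", "indelRate")) {
    v <- slot(object, nm)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, paste(nm, "must be a single value in [0, 1]"))
  }
  if (length(object@spatialProfile) && any(object@spatialProfile < 0))
    msgs <- c(msgs, "spatialProfile weights must be >= 0")
  if (length(object@spatialProfile) && sum(object@spatialProfile) <= 0)
    msgs <- c(msgs, "spatialProfile must have positive total weight")
  if (length(msgs)) msgs else TRUE
})
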