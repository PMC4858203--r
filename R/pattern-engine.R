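#' Construct an interspersed-homology pattern
#'
#' @param X integer, homologous unit length in bp (>= 0).
#' @param Y integer, spacer (non-homology) length in bp (>= 0); X + Y >= 1.
#' @param Z integer, 1-based sequence position of the first homologous unit.
#' @param L integer, region length in bp.
#' @param endPolicy `"truncate"` (default) or `"extend"`; see
#'   [HomologyPattern-class].
#' @param extendBy integer >= 0, extra bp appended to the final unit when
#'   `endPolicy = "extend"`.
#'
#' @return A [HomologyPattern-class] object.
#' @examples
#' p <- HomologyPattern(4, 7, Z = 1, L = 550)
#' patternName(p)
#' head(homologousPositions(p), 10)
#' @export
HomologyPattern <- function(X, Y, Z = 1L, L, endPolicy = c("truncate", "extend"),
                            extendBy = 0L) {
  endPolicy <- match.arg(endPolicy)
  new("HomologyPattern",
      unitLen = as.integer(X), spacerLen = as.integer(Y),
      seqPos = as.integer(Z), regionLen = as.integer(L),
      endPolicy = endPolicy, extendBy = as.integer(extendBy))
}

#' Perfect-homology pattern over a whole region
#'
#' Convenience constructor for a pattern whose every position is homologous
#' (a single unit spanning the region).
#'
#' @param L integer region length in bp.
#' @return A [HomologyPattern-class] with X = L, Y = 0, Z = 1.
#' @export
perfectPattern <- function(L) HomologyPattern(X = L, Y = 0L, Z = 1L, L = L)

#' @rdname accessors
#' @param x an object of the relevant class.
#' @export
setMethod("patternName", "HomologyPattern", function(x) {
  sprintf("%dH-%dN_%d", x@unitLen, x@spacerLen, x@seqPos)
})

#' Homologous positions of a pattern or cassette
#'
#' For a [HomologyPattern-class], computes the exact set of 1-based positions
#' covered by homologous units: units of X bp start at Z, Z + P, Z + 2P, ...
#' (P = X + Y), clipped to the region `[1, L]` according to the pattern's end
#' policy. For a [Cassette-class], returns the positions where the homology
#' mask is `TRUE`.
#'
#' @param x a [HomologyPattern-class] or [Cassette-class].
#' @param ... unused.
#' @return Sorted integer vector of 1-based positions. A pattern whose first
#'   unit starts beyond the region (Z > L) yields an empty set with a
#'   warning; X = 0 yields an empty set silently.
#' @examples
#' homologousPositions(HomologyPattern(4, 7, Z = 1, L = 23))
#' @export
setMethod("homologousPositions", "HomologyPattern", function(x, ...) {
  X <- x@unitLen; Y <- x@spacerLen; Z <- x@seqPos; L <- x@regionLen
  if (Z > L) {
    warning("first homologous unit starts beyond the region (Z = ", Z,
            " > L = ", L, "); no homologous positions", call. = FALSE)
    return(integer(0))
  }
  if (X == 0) return(integer(0))
  P <- X + Y
  starts <- seq.int(Z, L, by = P)
  pos <- rep(starts, each = X) + rep.int(seq_len(X) - 1L, length(starts))
  if (x@endPolicy == "extend" && x@extendBy > 0) {
    lastStart <- starts[length(starts)]
    ext <- seq.int(lastStart + X, length.out = x@extendBy)
    pos <- c(pos, ext)
  }
  sort(unique(pos[pos <= L]))
})

#' @rdname homologousPositions
#' @export
setMethod("homologousPositions", "Cassette", function(x, ...) {
  which(x@homologyMask)
})

#' Homology mask of a pattern or cassette
#'
#' @param x a [HomologyPattern-class] (mask computed over its region) or a
#'   [Cassette-class] (stored mask).
#' @param ... unused.
#' @return Logical vector, `TRUE` at homologous positions.
#' @export
setMethod("homologyMask", "HomologyPattern", function(x, ...) {
  mask <- logical(x@regionLen)
  mask[homologousPositions(x)] <- TRUE
  mask
})

#' @rdname homologyMask
#' @export
setMethod("homologyMask", "Cassette", function(x, ...) x@homologyMask)

#' Construct a cassette from two aligned sequences
#'
#' The homology mask is derived from position-wise equality, which the class
#' invariant makes the only consistent choice.
#'
#' @param referenceCopy,testCopy equal-length DNA sequences
#'   ([Biostrings::DNAString] or character), A/C/G/T only.
#' @param id character label.
#' @param provenance list of free-form provenance.
#' @return A [Cassette-class].
#' @export
Cassette <- function(referenceCopy, testCopy, id = "cassette",
                     provenance = list()) {
  refc <- .asDnaChars(referenceCopy, "referenceCopy")
  tstc <- .asDnaChars(testCopy, "testCopy")
  if (length(refc) != length(tstc)) {
    stop("reference (", length(refc), " bp) and test (", length(tstc),
         " bp) copies must have equal length", call. = FALSE)
  }
  new("Cassette",
      referenceCopy = .charsToDNAString(refc),
      testCopy = .charsToDNAString(tstc),
      homologyMask = refc == tstc,
      id = id, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("referenceCopy", "Cassette", function(x) x@referenceCopy)

#' @rdname accessors
#' @export
setMethod("testCopy", "Cassette", function(x) x@testCopy)

#' Generate a test sequence realizing a homology pattern
#'
#' Creates the designed "right" (test) copy of a repeat against a fixed
#' reference: at every homologous position of the pattern the test base
#' equals the reference base; at every other position the reference base is
#' substituted by one of the three alternative bases, chosen with equal
#' probabilities and independently of neighboring bases. Identical
#' (reference, pattern, seed) triples reproduce byte-identical output.
#'
#' @param reference [Biostrings::DNAString] or character, length must equal
#'   the pattern's region length.
#' @param pattern a [HomologyPattern-class] (use [perfectPattern()] for full
#'   homology).
#' @param seed integer seed for the substitution draws.
#' @return A [Cassette-class].
#' @examples
#' ref <- paste(sample(c("A", "C", "G", "T"), 55, replace = TRUE), collapse = "")
#' cas <- generateTest(ref, HomologyPattern(4, 7, 1, 55), seed = 1)
#' percentIdentity(cas)
#' @export
generateTest <- function(reference, pattern, seed) {
  stopifnot(is(pattern, "HomologyPattern"))
  refc <- .asDnaChars(reference, "reference")
  if (length(refc) != pattern@regionLen) {
    stop("reference length (", length(refc),
         ") must equal the pattern region length (", pattern@regionLen, ")",
         call. = FALSE)
  }
  mask <- homologyMask(pattern)
  tstc <- refc
  idx <- which(!mask)
  if (length(idx)) {
    tstc[idx] <- .withSeed(seed, .randomMismatch(refc[idx]))
  }
  new("Cassette",
      referenceCopy = .charsToDNAString(refc),
      testCopy = .charsToDNAString(tstc),
      homologyMask = mask,
      id = patternName(pattern),
      provenance = list(pattern = pattern, seed = seed))
}

#' Percent identity of two aligned sequences
#'
#' Fraction of positions at which two equal-length sequences carry the same
#' base. For a [Cassette-class], the identity of its test copy to its
#' reference copy (equivalently, the homologous fraction of its mask).
#'
#' @param a,b equal-length DNA sequences (DNAString or character), or `a` a
#'   [Cassette-class] with `b` missing.
#' @return Numeric fraction in \[0, 1\].
#' @examples
#' percentIdentity("ACGT", "ACGA")
#' @export
percentIdentity <- function(a, b) {
  if (missing(b)) {
    stopifnot(is(a, "Cassette"))
    return(mean(a@homologyMask))
  }
  ac <- .asDnaChars(a, "a")
  bc <- .asDnaChars(b, "b")
  if (length(ac) != length(bc)) {
    stop("sequences must have equal length (a: ", length(ac), " bp, b: ",
         length(bc), " bp)", call. = FALSE)
  }
  mean(ac == bc)
}

# Choose, for a triplet window starting at offset s of a homologous run with
# windows `allStarts`, the base position to edit: the triplet base covered by
# the fewest *other* windows of the same run (zero-coverage if one exists).
# Returns list(pos, shared) where shared = TRUE when no private base exists.
.chooseEditPosition <- function(s, allStarts) {
  others <- setdiff(allStarts, s)
  cand <- s:(s + 2L)
  cover <- vapply(cand, function(p)
    sum(others <= p & others + 2L >= p), integer(1))
  best <- cand[cover == min(cover)][1]
  list(pos = best, shared = min(cover) > 0)
}

#' Delete a triplet from homologous units by single-base complement edits
#'
#' Destroys occurrences of a target triplet inside the homologous units of a
#' cassette while preserving the units' other overlapping triplets, by
#' substituting exactly one base of each occurrence with its complement in
#' the test copy. Occurrences are found in both orientations (the triplet and
#' its reverse complement, matching the pooled census of
#' [enumerateUnitTriplets()]) within maximal homologous runs; windows
#' spanning a run boundary are never targeted. The edited base is the one
#' not shared with any other triplet window of the run — for a 4-bp unit this
#' reproduces the two worked rules: a `GAC` at unit positions 1-3 is edited
#' at position 1 (G to C) and a `GAC` at positions 2-4 at position 4 (C to
#' G). If every base of an occurrence is shared with another window, the
#' least-shared base is edited anyway and a message is logged. Edited
#' positions become non-homologous in the mask.
#'
#' @param cassette a [Cassette-class].
#' @param triplet character 3-mer over A/C/G/T.
#' @param occurrences `"all"` (default) or an integer: edit only the first n
#'   occurrences in sequence order.
#' @return The edited [Cassette-class]; edits are recorded in
#'   `provenance$edits` (data.frame of position, from, to).
#' @examples
#' cas <- Cassette("GACTAAAAAAA", "GACTCCGCCGC")  # one 4-bp unit "GACT"
#' edited <- deleteUnitTriplet(cas, "GAC")
#' as.character(testCopy(edited))
#' @export
deleteUnitTriplet <- function(cassette, triplet, occurrences = "all") {
  stopifnot(is(cassette, "Cassette"))
  tri <- .asDnaChars(triplet, "triplet")
  if (length(tri) != 3) stop("triplet must have length 3", call. = FALSE)
  targetFwd <- paste(tri, collapse = "")
  targetRev <- paste(.reverseComplementChars(tri), collapse = "")
  targets <- unique(c(targetFwd, targetRev))

  refc <- strsplit(as.character(cassette@referenceCopy), "")[[1]]
  tstc <- strsplit(as.character(cassette@testCopy), "")[[1]]
  mask <- cassette@homologyMask
  runs <- .maskRuns(mask)
  runs <- runs[runs$width >= 3, , drop = FALSE]

  occ <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    starts <- a:(b - 2L)
    words <- vapply(starts, function(s)
      paste(refc[s:(s + 2L)], collapse = ""), character(1))
    hit <- starts[words %in% targets]
    for (s in hit) occ[[length(occ) + 1L]] <- list(s = s, starts = starts)
  }
  if (length(occ) == 0) return(cassette)
  ord <- order(vapply(occ, `[[`, integer(1), "s"))
  occ <- occ[ord]
  if (is.numeric(occurrences)) {
    occ <- occ[seq_len(min(length(occ), as.integer(occurrences)))]
  } else if (!identical(occurrences, "all")) {
    stop("occurrences must be \"all\" or an integer", call. = FALSE)
  }

  editPos <- integer(0)
  for (o in occ) {
    ch <- .chooseEditPosition(o$s, o$starts)
    if (ch$shared) {
      message("triplet occurrence at position ", o$s,
              " shares every base with another window; editing position ",
              ch$pos, " anyway")
    }
    editPos <- c(editPos, ch$pos)
  }
  editPos <- unique(editPos)
  from <- tstc[editPos]
  tstc[editPos] <- unname(.COMPLEMENT[tstc[editPos]])
  mask[editPos] <- FALSE

  prov <- cassette@provenance
  prov$edits <- rbind(prov$edits,
    data.frame(position = editPos, from = from, to = tstc[editPos],
               triplet = targetFwd, stringsAsFactors = FALSE))
  new("Cassette",
      referenceCopy = cassette@referenceCopy,
      testCopy = .charsToDNAString(tstc),
      homologyMask = mask,
      id = cassette@id,
      provenance = prov)
}

#' Construct a cassette composition specification
#'
#' @param reference reference sequence for the main region (DNAString or
#'   character); its length is the region length L.
#' @param pattern500 [HomologyPattern-class] or `"perfect"` for the main
#'   region.
#' @param blockLen integer block length in bp (0 for none). The study used
#'   0, 15, 25, 50, 75 and 100 bp; any length is accepted.
#' @param blockSide `"left"`, `"right"` or `"none"`.
#' @param blockPattern [HomologyPattern-class] or `"perfect"` (default) for
#'   the block.
#' @param blockReference optional DNAString/character of length `blockLen`;
#'   sampled from a child stream of the composition seed when `NULL`.
#' @param junctionInsertLen integer >= 0 bp of random non-homology inserted
#'   at the block/region junction.
#' @param interruption `NULL`, or `c(start, len)` (1-based within the block)
#'   to replace with non-matching bases.
#' @return A [CassetteSpec-class].
#' @export
CassetteSpec <- function(reference, pattern500 = "perfect", blockLen = 0L,
                         blockSide = c("none", "left", "right"),
                         blockPattern = "perfect", blockReference = NULL,
                         junctionInsertLen = 0L, interruption = NULL) {
  blockSide <- match.arg(blockSide)
  if (!is.null(blockReference) && !is(blockReference, "DNAString")) {
    blockReference <- .charsToDNAString(.asDnaChars(blockReference,
                                                    "blockReference"))
  }
  new("CassetteSpec",
      reference = .charsToDNAString(.asDnaChars(reference, "reference")),
      pattern500 = pattern500,
      blockLen = as.integer(blockLen),
      blockSide = blockSide,
      blockPattern = blockPattern,
      blockReference = blockReference,
      junctionInsertLen = as.integer(junctionInsertLen),
      interruption = if (is.null(interruption)) integer(0)
                     else as.integer(interruption))
}

# Realize one component (region or block) of a composition.
.realizeComponent <- function(reference, pattern, seed, tag) {
  L <- length(reference)
  if (identical(pattern, "perfect")) pattern <- perfectPattern(L)
  generateTest(reference, pattern, .childSeed(seed, tag))
}

#' Compose a full repeat cassette from a specification
#'
#' Assembles, in order along the construct, the adjacent block (on its
#' specified side), the optional random junction insert, and the main
#' patterned region, and returns the realized cassette with a homology mask
#' reflecting every component. The junction insert is non-homologous by
#' construction: its test base differs from its reference base at every
#' position. An interruption replaces the specified sub-segment of the block
#' with non-matching test bases, splitting the block's perfect homology. The
#' total length is `L + blockLen + junctionInsertLen`.
#'
#' Each component draws from its own child stream of `seed`, so adding or
#' resizing a block never perturbs the main region's sequence.
#'
#' @param spec a [CassetteSpec-class].
#' @param seed integer top-level seed.
#' @return A [Cassette-class]; `provenance` records the [CassetteSpec-class],
#'   the seed and the
#'   1-based coordinate ranges of each component.
#' @export
composeCassette <- function(spec, seed) {
  stopifnot(is(spec, "CassetteSpec"))
  validObject(spec)
  region <- .realizeComponent(spec@reference, spec@pattern500, seed, "region")
  regRef <- strsplit(as.character(region@referenceCopy), "")[[1]]
  regTst <- strsplit(as.character(region@testCopy), "")[[1]]

  blkRef <- blkTst <- character(0)
  if (spec@blockLen > 0) {
    blockReference <- spec@blockReference
    if (is.null(blockReference)) {
      blockReference <- .charsToDNAString(
        .withSeed(.childSeed(seed, "block-ref"), .randomBases(spec@blockLen)))
    }
    blk <- .realizeComponent(blockReference, spec@blockPattern, seed, "block")
    blkRef <- strsplit(as.character(blk@referenceCopy), "")[[1]]
    blkTst <- strsplit(as.character(blk@testCopy), "")[[1]]
    if (length(spec@interruption) == 2) {
      it <- seq.int(spec@interruption[1], length.out = spec@interruption[2])
      blkTst[it] <- .withSeed(.childSeed(seed, "interruption"),
                              .randomMismatch(blkRef[it]))
    }
  }

  insRef <- insTst <- character(0)
  if (spec@junctionInsertLen > 0) {
    insRef <- .withSeed(.childSeed(seed, "junction-ref"),
                        .randomBases(spec@junctionInsertLen))
    insTst <- .withSeed(.childSeed(seed, "junction-test"),
                        .randomMismatch(insRef))
  }

  if (spec@blockSide == "right") {
    refc <- c(regRef, insRef, blkRef)
    tstc <- c(regTst, insTst, blkTst)
    layout <- list(region = c(1L, length(regRef)),
                   insert = c(length(regRef) + 1L,
                              length(regRef) + length(insRef)),
                   block = c(length(regRef) + length(insRef) + 1L,
                             length(refc)))
  } else {
    refc <- c(blkRef, insRef, regRef)
    tstc <- c(blkTst, insTst, regTst)
    layout <- list(block = c(1L, length(blkRef)),
                   insert = c(length(blkRef) + 1L,
                              length(blkRef) + length(insRef)),
                   region = c(length(blkRef) + length(insRef) + 1L,
                              length(refc)))
  }

  idBits <- c(if (identical(spec@pattern500, "perfect")) "perfect"
              else patternName(spec@pattern500),
              if (spec@blockLen > 0) paste0("b", spec@blockLen,
                                            substr(spec@blockSide, 1, 1)),
              if (spec@junctionInsertLen > 0) paste0("j", spec@junctionInsertLen),
              if (length(spec@interruption)) paste0("i", spec@interruption[1],
                                                    "+", spec@interruption[2]))
  new("Cassette",
      referenceCopy = .charsToDNAString(refc),
      testCopy = .charsToDNAString(tstc),
      homologyMask = refc == tstc,
      id = paste(idBits, collapse = "_"),
      provenance = list(spec = spec, seed = seed, layout = layout))
}
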