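# Internal helpers: deterministic child RNG streams and sequence plumbing.

DNA_BASES <- c("A", "C", "G", "T")

# For each base, the three alternative bases (columns), used when forcing a
# mismatch with uniform probability over the alternatives.
.ALT_BASES <- rbind(
  A = c("C", "G", "T"),
  C = c("A", "G", "T"),
  G = c("A", "C", "T"),
  T = c("A", "C", "G")
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @importFrom methods is new validObject slot
NULL

# Deterministic per-component seed derived from a top-level seed and a tag.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it, and
# guarantees that adding a component (new tag) never perturbs the streams of
# existing components.
.childSeed <- function(seed, tag) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  s <- ((as.numeric(seed) %% m) * 69069 + h) %% m
  as.integer(if (s == 0) 1 else s)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Coerce to a plain uppercase character string of A/C/G/T; errors name the
# first offending position.
.asDnaChars <- function(x, what = "sequence") {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1) {
    stop(what, " must be a single DNA sequence", call. = FALSE)
  }
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0) {
    stop(what, " contains a non-ACGT character ('", chars[bad[1]],
         "') at position ", bad[1], call. = FALSE)
  }
  chars
}

.charsToDNAString <- function(chars) {
  Biostrings::DNAString(paste(chars, collapse = ""))
}

# Maximal runs of TRUE in a logical mask, as a data.frame(start, end, width).
.maskRuns <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             width = r$lengths[keep])
}

# Draw n bases uniformly from {A,C,G,T} (uses the current RNG stream).
.randomBases <- function(n) {
  DNA_BASES[sample.int(4L, n, replace = TRUE)]
}

# For each reference base, draw a base guaranteed to differ, uniformly over
# the three alternatives (uses the current RNG stream).
.randomMismatch <- function(refChars) {
  n <- length(refChars)
  if (n == 0) return(character(0))
  pick <- sample.int(3L, n, replace = TRUE)
  .ALT_BASES[cbind(match(refChars, DNA_BASES), pick)]
}

.reverseComplementChars <- function(chars) {
  rev(unname(.COMPLEMENT[chars]))
}
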