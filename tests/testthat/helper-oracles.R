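# Independent brute-force oracles and small fixture builders. Each oracle is
# a direct transcription of the defining rule, kept deliberately naive and
# separate from the package's implementations.

randomReference <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Homologous positions by direct enumeration of unit index k and offset j:
# positions Z + k(X+Y) + j for j < X, intersected with [1, L]; under the
# extend policy the final unit gains extendBy extra positions (clipped).
bfHomologousPositions <- function(X, Y, Z, L, endPolicy = "truncate",
                                  extendBy = 0) {
  if (X == 0 || Z > L) return(integer(0))
  P <- X + Y
  pos <- integer(0)
  lastStart <- NA
  k <- 0
  repeat {
    start <- Z + k * P
    if (start > L) break
    lastStart <- start
    for (j in 0:(X - 1)) {
      p <- start + j
      if (p <= L) pos <- c(pos, p)
    }
    k <- k + 1
  }
  if (endPolicy == "extend" && extendBy > 0 && !is.na(lastStart)) {
    for (j in seq_len(extendBy)) {
      p <- lastStart + X + j - 1
      if (p <= L) pos <- c(pos, p)
    }
  }
  as.integer(sort(unique(pos)))
}

# Triplet census by scanning every 3-bp window that lies entirely inside the
# homology mask, counting the reference word pooled with its reverse
# complement under the lexicographically smaller name.
bfRevComp <- function(word) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(word, "")[[1]]]), collapse = "")
}

bfCanonical <- function(word) {
  rc <- bfRevComp(word)
  if (word <= rc) word else rc
}

bfCensus <- function(cassette) {
  refc <- strsplit(as.character(referenceCopy(cassette)), "")[[1]]
  mask <- homologyMask(cassette)
  counts <- structure(integer(0), names = character(0))
  L <- length(mask)
  if (L >= 3) {
    for (i in 1:(L - 2)) {
      if (all(mask[i:(i + 2)])) {
        w <- bfCanonical(paste(refc[i:(i + 2)], collapse = ""))
        counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
      }
    }
  }
  counts
}

# Two-sample KS by full enumeration of all C(n+m, n) label assignments of
# the pooled values; D evaluated at the pooled unique values; the p-value is
# the fraction of assignments at least as extreme as the observed D.
bfKsD <- function(a, b) {
  z <- sort(unique(c(a, b)))
  Fa <- vapply(z, function(q) mean(a <= q), numeric(1))
  Fb <- vapply(z, function(q) mean(b <= q), numeric(1))
  max(abs(Fa - Fb))
}

bfKsExactP <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  dObs <- bfKsD(a, b)
  combos <- utils::combn(length(pooled), n)
  ds <- apply(combos, 2, function(idx) bfKsD(pooled[idx], pooled[-idx]))
  mean(ds >= dObs - 1e-9)
}

# A cassette whose first homologous unit is a chosen 4-mer, padded with A's
# (which stay non-homologous thanks to forced mismatches elsewhere).
unitCassette <- function(unit, Y = 7, L = 11, seed = 1) {
  ref <- paste0(unit, paste(rep("A", L - nchar(unit)), collapse = ""))
  generateTest(ref, HomologyPattern(nchar(unit), Y, 1, L), seed = seed)
}
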