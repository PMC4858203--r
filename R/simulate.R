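#' Construct a RIP simulation model
#'
#' @param lambdaMean numeric >= 0, expected mutations per non-escaping spore
#'   (the study's constructs span roughly 0-25 per spore).
#' @param escapeProb numeric in \[0, 1\], fraction of spores with no RIP at
#'   all (default 0).
#' @param spatialProfile optional numeric weight per position; when `NULL` a
#'   symmetric triangular profile peaking at the sequence center is used,
#'   emulating the concentration of mutations near the middle of compound
#'   repeats.
#' @param ctGaRatio numeric in \[0, 1\], probability that a mutation is
#'   C-to-T rather than G-to-A (default 0.5).
#' @param indelRate numeric in \[0, 1\], per-position deletion probability
#'   applied after mutagenesis (default 0; RIP itself makes no indels).
#' @return A [RipSimModel-class].
#' @export
RipSimModel <- function(lambdaMean = 10, escapeProb = 0, spatialProfile = NULL,
                        ctGaRatio = 0.5, indelRate = 0) {
  new("RipSimModel",
      lambdaMean = as.numeric(lambdaMean),
      escapeProb = as.numeric(escapeProb),
      spatialProfile = if (is.null(spatialProfile)) numeric(0)
                       else as.numeric(spatialProfile),
      ctGaRatio = as.numeric(ctGaRatio),
      indelRate = as.numeric(indelRate))
}

# Symmetric triangular weight profile peaking at the center of an L-bp
# sequence; strictly positive everywhere so no site is categorically
# excluded.
.triangularProfile <- function(L) {
  center <- (L + 1) / 2
  1 - abs(seq_len(L) - center) / center
}

#' Simulate RIP-mutated spore contigs with planted mutations
#'
#' Generates Sanger-style spore contigs for a cassette under a
#' [RipSimModel-class]: per spore, an escape draw, a Poisson mutation count,
#' a C-to-T/G-to-A class split, and weighted placement (without replacement)
#' among the class's mutable sites — reference C's for C-to-T, reference G's
#' for G-to-A — with site probabilities proportional to the spatial profile.
#' Sequences are emitted in reference-copy coordinates, the coordinate
#' system in which per-site profiles are expressed. The planted calls are
#' returned as ground truth, so calling can be validated exactly. If a drawn
#' count exceeds the available mutable sites of its class it is truncated
#' with a log message. Output is deterministic for a given seed.
#'
#' @param cassette a [Cassette-class]; spores mutate its reference copy.
#' @param model a [RipSimModel-class].
#' @param nSpores integer number of spores.
#' @param seed integer seed.
#' @param construct character RepeatID used in spore identifiers (letters
#'   only, so `"{RepeatID}{cross}_{spore}"` stays parseable).
#' @param cross integer replica-cross index used in spore identifiers.
#' @return `list(spores, planted)`: `spores` a named
#'   [Biostrings::DNAStringSet] and `planted` a list of
#'   [MutationCallSet-class] ground truth, in the same order.
#' @examples
#' ref <- paste(rep(c("C", "G", "A", "T"), 25), collapse = "")
#' cas <- generateTest(ref, perfectPattern(100), seed = 1)
#' sim <- simulateSpores(cas, RipSimModel(lambdaMean = 5), 10, seed = 42)
#' names(sim$spores)[1:3]
#' @export
simulateSpores <- function(cassette, model, nSpores, seed,
                           construct = "SIM", cross = 1L) {
  stopifnot(is(cassette, "Cassette"), is(model, "RipSimModel"), nSpores >= 1)
  refc <- strsplit(as.character(cassette@referenceCopy), "")[[1]]
  L <- length(refc)
  w <- if (length(model@spatialProfile)) {
    if (length(model@spatialProfile) != L) {
      stop("spatialProfile length (", length(model@spatialProfile),
           ") must equal the sequence length (", L, ")", call. = FALSE)
    }
    model@spatialProfile
  } else {
    .triangularProfile(L)
  }
  cSites <- which(refc == "C")
  gSites <- which(refc == "G")

  drawSites <- function(sites, n) {
    if (n == 0 || length(sites) == 0) return(integer(0))
    if (n > length(sites)) {
      message("requested ", n, " mutations but only ", length(sites),
              " mutable sites available; truncating")
      n <- length(sites)
    }
    if (length(sites) == 1) return(sites)
    sites[sample.int(length(sites), n, prob = w[sites])]
  }

  .withSeed(seed, {
    spores <- character(nSpores)
    planted <- vector("list", nSpores)
    ids <- sprintf("%s%d_%d", construct, cross, seq_len(nSpores))
    for (i in seq_len(nSpores)) {
      chars <- refc
      posCT <- posGA <- integer(0)
      if (stats::runif(1) >= model@escapeProb && model@lambdaMean > 0) {
        nMut <- stats::rpois(1, model@lambdaMean)
        nCT <- stats::rbinom(1, nMut, model@ctGaRatio)
        posCT <- drawSites(cSites, nCT)
        posGA <- drawSites(gSites, nMut - nCT)
        chars[posCT] <- "T"
        chars[posGA] <- "A"
      }
      ord <- order(c(posCT, posGA))
      planted[[i]] <- new("MutationCallSet",
        sporeId = ids[i],
        positions = as.integer(c(posCT, posGA)[ord]),
        classes = c(rep("CT", length(posCT)), rep("GA", length(posGA)))[ord],
        refLength = L)
      if (model@indelRate > 0) {
        chars <- chars[stats::runif(L) >= model@indelRate]
      }
      spores[i] <- paste(chars, collapse = "")
    }
    set <- Biostrings::DNAStringSet(spores)
    names(set) <- ids
    list(spores = set, planted = planted)
  })
}

#' Illustrative per-construct intensity table
#'
#' A small synthetic manifest of constructs with per-construct mean mutation
#' intensities, loosely shaped like the spread observed across real repeat
#' constructs (a near-silent interspersed homology, a strongly mutated one,
#' and intermediate block-assisted levels). Purely illustrative: the
#' RepeatIDs are synthetic (`SIMA`...) and the intensities are not
#' measurements.
#'
#' @return data.frame with columns `repeatId`, `description`, `X`, `Y`, `Z`,
#'   `L`, `lambda`, `escapeProb`.
#' @export
studyManifest <- function() {
  path <- system.file("extdata", "illustrative_lambda_table.tsv",
                      package = "RIPforge", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Emulate a spore-sequencing study end to end
#'
#' Generates, for each construct of a manifest, a reference segment, its
#' patterned cassette, and replica crosses of simulated spores, and writes
#' the dataset in the file shapes of a spore-resequencing study: a 4-field
#' contig CSV (id, C/T count, G/A count, sequence), one expected-cassette
#' FASTA per construct, a construct table, and a planted-call ground-truth
#' TSV. The recorded CSV counts are the planted truths, so re-calling the
#' contigs must reproduce them exactly.
#'
#' @param manifest data.frame as from [studyManifest()]: columns `repeatId`
#'   (letters only), `X`, `Y`, `Z`, `L`, `lambda`, optional `escapeProb` and
#'   `description`.
#' @param dir output directory (created if needed).
#' @param nCrosses integer replica crosses per construct (default 2).
#' @param nSporesPerCross integer spores per cross (default 30).
#' @param seed integer top-level seed; every construct and cross draws from
#'   its own child stream.
#' @return Invisibly, `list(csv, constructs, truth, expectedDir, calls)`
#'   with file paths and the in-memory per-spore table.
#' @export
emulateStudy <- function(manifest, dir, nCrosses = 2L, nSporesPerCross = 30L,
                         seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("repeatId", "X", "Y", "Z", "L", "lambda") %in%
                names(manifest)))
  if (any(grepl("[^A-Za-z]", manifest$repeatId))) {
    stop("repeatId must contain letters only so spore ids stay parseable",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expectedDir <- file.path(dir, "expected")
  dir.create(expectedDir, showWarnings = FALSE)

  rows <- list()
  truthRows <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    refSeed <- .childSeed(seed, paste0("ref-", m$repeatId))
    ref <- paste(.withSeed(refSeed, .randomBases(m$L)), collapse = "")
    cas <- generateTest(ref, HomologyPattern(m$X, m$Y, m$Z, m$L),
                        seed = .childSeed(seed, paste0("test-", m$repeatId)))
    fa <- Biostrings::DNAStringSet(as.character(cas@referenceCopy))
    names(fa) <- paste0(m$repeatId, " expected cassette (reference copy)")
    Biostrings::writeXStringSet(fa,
      filepath = file.path(expectedDir, paste0(m$repeatId, ".fasta")),
      width = 70)
    esc <- if ("escapeProb" %in% names(m) && !is.na(m$escapeProb))
      m$escapeProb else 0
    model <- RipSimModel(lambdaMean = m$lambda, escapeProb = esc)
    for (cr in seq_len(nCrosses)) {
      sim <- simulateSpores(cas, model, nSporesPerCross,
                            seed = .childSeed(seed,
                                              paste0(m$repeatId, "-", cr)),
                            construct = m$repeatId, cross = cr)
      for (i in seq_along(sim$planted)) {
        pl <- sim$planted[[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          id = pl@sporeId, n_CT = nCT(pl), n_GA = nGA(pl),
          seq = as.character(sim$spores[[i]]), stringsAsFactors = FALSE)
        if (length(pl@positions)) {
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            spore_id = pl@sporeId, position = pl@positions,
            class = pl@classes, stringsAsFactors = FALSE)
        }
      }
    }
  }
  calls <- do.call(rbind, rows)
  csvPath <- file.path(dir, "contigs.csv")
  utils::write.table(calls, csvPath, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- do.call(rbind, c(truthRows, list(
    data.frame(spore_id = character(0), position = integer(0),
               class = character(0)))))
  truthPath <- file.path(dir, "planted_calls.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  constructsPath <- file.path(dir, "constructs.tsv")
  out <- manifest
  out$nCrosses <- nCrosses
  out$nSpores <- nCrosses * nSporesPerCross
  utils::write.table(out, constructsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(csv = csvPath, constructs = constructsPath,
                 truth = truthPath, expectedDir = expectedDir,
                 calls = calls))
}
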