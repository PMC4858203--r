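test_that("positional calling classifies substitutions directly", {
  expect_equal(nCT(callMutations("ACGT", "ACGT")), 0)
  expect_equal(nGA(callMutations("ACGT", "ACGT")), 0)

  calls <- callMutations("CCGG", "TCGA")
  expect_equal(nCT(calls), 1)
  expect_equal(nGA(calls), 1)
  expect_equal(nOther(calls), 0)
  expect_identical(mutationPositions(calls), c(1L, 4L))
  expect_identical(mutationClasses(calls), c("CT", "GA"))

  # a T->C change is not RIP: counted as other, excluded from RIP totals
  other <- callMutations("TTTT", "TCTT")
  expect_equal(nOther(other), 1)
  expect_equal(meanMutations(list(other))$mean, 0)

  expect_error(callMutations("ACGT", "ACGTA"), "equal lengths")
})

test_that("gapped calling excludes gap columns and keeps expected coordinates", {
  # spore has a 2-bp insertion after position 4 and a C>T at position 6
  expected <- "ACGTACGTACGT"
  spore    <- "ACGTTTATGTACGT"
  expect_message(
    calls <- callMutations(expected, spore, mode = "gapped"),
    "gap column")
  expect_identical(mutationClasses(calls), "CT")
  expect_identical(mutationPositions(calls), 6L)

  # a grossly misassigned spore (mostly gaps) is rejected
  expect_error(callMutations("ACGTACGTACGTACGTACGT", "ACG", mode = "gapped"),
               "gap columns")
})

test_that("simulate-then-call recovers planted mutations exactly", {
  ref <- randomReference(300, seed = 90)
  cas <- generateTest(ref, perfectPattern(300), seed = 1)
  sim <- simulateSpores(cas, RipSimModel(lambdaMean = 8), 25, seed = 17,
                        construct = "SIMA")
  for (i in seq_along(sim$planted)) {
    calls <- callMutations(referenceCopy(cas), sim$spores[[i]],
                           sporeId = names(sim$spores)[i])
    expect_identical(mutationPositions(calls),
                     mutationPositions(sim$planted[[i]]))
    expect_identical(mutationClasses(calls),
                     mutationClasses(sim$planted[[i]]))
  }
})

test_that("calling on the reverse complement swaps the CT and GA classes", {
  set.seed(33)
  for (i in 1:10) {
    ref <- randomReference(150, seed = 900 + i)
    cas <- generateTest(ref, perfectPattern(150), seed = 1)
    sim <- simulateSpores(cas, RipSimModel(lambdaMean = 6), 1, seed = i)
    fwd <- callMutations(referenceCopy(cas), sim$spores[[1]])
    rcExpected <- as.character(Biostrings::reverseComplement(referenceCopy(cas)))
    rcSpore <- as.character(Biostrings::reverseComplement(sim$spores[[1]]))
    rev <- callMutations(rcExpected, rcSpore)
    expect_equal(nCT(rev), nGA(fwd))
    expect_equal(nGA(rev), nCT(fwd))
    # positions mirror through L + 1 - pos
    expect_identical(sort(151L - mutationPositions(rev)),
                     sort(mutationPositions(fwd)))
  }
})

test_that("mean mutation summaries follow the mean/SEM definitions", {
  mkCalls <- function(totals, L = 100) {
    lapply(seq_along(totals), function(i) {
      n <- totals[i]
      new("MutationCallSet", sporeId = paste0("S", i),
          positions = if (n > 0) seq_len(n) else integer(0),
          classes = rep("CT", n), refLength = as.integer(L))
    })
  }
  r <- meanMutations(mkCalls(c(2, 4)))
  expect_equal(r$mean, 3)
  expect_equal(r$sem, 1)
  expect_equal(r$n, 2)

  z <- meanMutations(mkCalls(c(0, 0, 0)))
  expect_equal(z$mean, 0)
  expect_equal(z$sem, 0)

  one <- meanMutations(mkCalls(5))
  expect_equal(one$sem, 0)

  expect_error(meanMutations(list()), "empty")
})

test_that("region-restricted means are additive over a split", {
  ref <- randomReference(200, seed = 44)
  cas <- generateTest(ref, perfectPattern(200), seed = 1)
  sim <- simulateSpores(cas, RipSimModel(lambdaMean = 12), 20, seed = 3)
  calls <- lapply(seq_along(sim$spores), function(i)
    callMutations(referenceCopy(cas), sim$spores[[i]]))
  for (m in c(1, 50, 123, 199)) {
    whole <- meanMutations(calls, region = c(1, 200))$mean
    left <- meanMutations(calls, region = c(1, m))$mean
    right <- meanMutations(calls, region = c(m + 1, 200))$mean
    expect_equal(left + right, whole)
  }
  expect_equal(meanMutations(calls)$mean,
               meanMutations(calls, region = c(1, 200))$mean)
})

test_that("planted Poisson totals are recovered within sampling error", {
  ref <- randomReference(400, seed = 45)
  cas <- generateTest(ref, perfectPattern(400), seed = 1)
  sim <- simulateSpores(cas, RipSimModel(lambdaMean = 10), 30, seed = 21)
  calls <- lapply(seq_along(sim$spores), function(i)
    callMutations(referenceCopy(cas), sim$spores[[i]]))
  r <- meanMutations(calls)
  expect_lt(abs(r$mean - 10), 3 * r$sem)
})

test_that("site profiles count mutated spores per position", {
  # 2 of 30 spores mutated at site 7
  calls <- lapply(1:30, function(i) {
    mut <- i <= 2
    new("MutationCallSet", sporeId = paste0("S", i),
        positions = if (mut) 7L else integer(0),
        classes = if (mut) "CT" else character(0), refLength = 50L)
  })
  prof <- siteProfile(calls, length = 50)
  expect_equal(siteCounts(prof)[7], 2)
  expect_equal(round(sitePercent(prof)[7], 2), 6.67)
  expect_equal(nSpores(prof), 30)
  expect_true(all(siteCounts(prof)[-7] == 0))

  # total profile mass equals the sum of per-spore RIP totals
  ref <- randomReference(120, seed = 46)
  cas <- generateTest(ref, perfectPattern(120), seed = 1)
  sim <- simulateSpores(cas, RipSimModel(lambdaMean = 5), 40, seed = 8)
  simCalls <- lapply(seq_along(sim$spores), function(i)
    callMutations(referenceCopy(cas), sim$spores[[i]]))
  prof2 <- siteProfile(simCalls, length = 120)
  expect_equal(sum(siteCounts(prof2)),
               sum(vapply(simCalls, function(cs) nCT(cs) + nGA(cs),
                          numeric(1))))
})

test_that("a planted hot spot is recovered as the profile argmax", {
  L <- 200
  w <- rep(0.01, L)
  w[101] <- 50  # strong planted hot spot at site 101
  ref <- randomReference(L, seed = 47)
  substr(ref, 101, 101) <- "C"  # make the hot spot a mutable (C) site
  cas <- generateTest(ref, perfectPattern(L), seed = 1)
  model <- RipSimModel(lambdaMean = 3, spatialProfile = w)
  sim <- simulateSpores(cas, model, 200, seed = 14)
  calls <- lapply(seq_along(sim$spores), function(i)
    callMutations(referenceCopy(cas), sim$spores[[i]]))
  prof <- siteProfile(calls, length = L)
  expect_identical(which.max(siteCounts(prof)), 101L)
})
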