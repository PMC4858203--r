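test_that("homologous positions follow the unit/spacer/start definition", {
  expect_identical(homologousPositions(HomologyPattern(4, 7, 1, 23)),
                   c(1:4, 12:15, 23L))
  expect_identical(homologousPositions(HomologyPattern(4, 7, 7, 22)),
                   c(7:10, 18:21))
  # zero-length units give an empty set
  expect_identical(homologousPositions(HomologyPattern(0, 7, 1, 100)),
                   integer(0))
  # first unit beyond the region: empty with a warning, not an error
  expect_warning(
    pos <- homologousPositions(HomologyPattern(4, 7, 50, 20)),
    "beyond the region")
  expect_identical(pos, integer(0))
})

test_that("homologous positions match brute-force enumeration on random patterns", {
  set.seed(101)
  for (i in 1:300) {
    X <- sample(0:8, 1)
    Y <- sample(0:12, 1)
    if (X + Y == 0) Y <- 1
    Z <- sample(1:15, 1)
    L <- sample(1:120, 1)
    ext <- sample(0:3, 1)
    policy <- if (ext > 0) "extend" else "truncate"
    p <- HomologyPattern(X, Y, Z, L, endPolicy = policy, extendBy = ext)
    got <- suppressWarnings(homologousPositions(p))
    want <- bfHomologousPositions(X, Y, Z, L, policy, ext)
    expect_identical(got, want,
                     info = sprintf("X=%d Y=%d Z=%d L=%d ext=%d", X, Y, Z, L, ext))
  }
})

test_that("shifting the start by one period drops exactly the first unit", {
  set.seed(7)
  for (i in 1:50) {
    X <- sample(1:8, 1); Y <- sample(0:10, 1); Z <- sample(1:10, 1)
    L <- sample(60:200, 1)
    P <- X + Y
    p1 <- homologousPositions(HomologyPattern(X, Y, Z, L))
    p2 <- homologousPositions(HomologyPattern(X, Y, Z + P, L))
    firstUnit <- p1[p1 < Z + P]
    expect_identical(p2, setdiff(p1, firstUnit))
  }
})

test_that("the extend policy lengthens only the final unit", {
  # a pattern whose last unit was accidentally extended by 3 bp
  p <- HomologyPattern(6, 4, 2, 100, endPolicy = "extend", extendBy = 3)
  base <- homologousPositions(HomologyPattern(6, 4, 2, 100))
  got <- homologousPositions(p)
  lastStart <- max(base[c(TRUE, diff(base) > 1)])
  expect_identical(setdiff(got, base),
                   intersect((lastStart + 6):(lastStart + 8), 1:100))
})

test_that("generated test copies honor the mask at every position", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(30:200, 1)
    ref <- randomReference(L, seed = 1000 + i)
    p <- HomologyPattern(sample(1:6, 1), sample(1:9, 1), sample(1:5, 1), L)
    cas <- generateTest(ref, p, seed = i)
    refc <- strsplit(as.character(referenceCopy(cas)), "")[[1]]
    tstc <- strsplit(as.character(testCopy(cas)), "")[[1]]
    expect_identical(refc == tstc, homologyMask(cas))
    expect_identical(homologyMask(cas), homologyMask(p))
    # mismatch fraction at non-homologous positions is exactly 1
    expect_true(all(refc[!homologyMask(cas)] != tstc[!homologyMask(cas)]))
  }
})

test_that("generation is deterministic and seeds differ only off the mask", {
  ref <- randomReference(120, seed = 5)
  p <- HomologyPattern(4, 7, 1, 120)
  a <- generateTest(ref, p, seed = 42)
  b <- generateTest(ref, p, seed = 42)
  expect_identical(as.character(testCopy(a)), as.character(testCopy(b)))
  c <- generateTest(ref, p, seed = 43)
  diffPos <- which(strsplit(as.character(testCopy(a)), "")[[1]] !=
                   strsplit(as.character(testCopy(c)), "")[[1]])
  expect_true(all(!homologyMask(p)[diffPos]))
})

test_that("a perfect pattern reproduces the reference exactly", {
  ref <- randomReference(80, seed = 3)
  cas <- generateTest(ref, perfectPattern(80), seed = 1)
  expect_identical(as.character(testCopy(cas)), ref)
  expect_equal(percentIdentity(cas), 1)
})

test_that("substitutions are uniform over the three alternative bases", {
  ref <- paste(rep("A", 12000), collapse = "")
  cas <- generateTest(ref, HomologyPattern(0, 1, 1, 12000), seed = 99)
  tstc <- strsplit(as.character(testCopy(cas)), "")[[1]]
  tab <- table(tstc)
  expect_setequal(names(tab), c("C", "G", "T"))
  n <- length(tstc)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (f in tab / n) expect_lt(abs(f - 1 / 3), 3 * se)
})

test_that("generation rejects non-ACGT references naming the position", {
  expect_error(generateTest("ACGNT", HomologyPattern(1, 1, 1, 5), seed = 1),
               "position 4")
})

test_that("percent identity counts equal positions", {
  expect_equal(percentIdentity("ACGT", "ACGT"), 1)
  expect_equal(percentIdentity("ACGT", "TGCA"), 0)
  expect_error(percentIdentity("ACGT", "ACGTA"), "4.*5")
  ref <- randomReference(550, seed = 8)
  cas <- generateTest(ref, HomologyPattern(4, 7, 1, 550), seed = 2)
  expect_equal(percentIdentity(cas), 200 / 550)
  expect_equal(sum(homologyMask(cas)),
               length(bfHomologousPositions(4, 7, 1, 550)))
})

test_that("triplet deletion reproduces both single-base edit rules", {
  # GAC occupying unit positions 1-3: edit position 1, G -> C
  cas <- unitCassette("GACT")
  ed <- deleteUnitTriplet(cas, "GAC")
  expect_identical(substr(as.character(testCopy(ed)), 1, 4), "CACT")
  # the other overlapping triplet of the unit is untouched
  expect_identical(substr(as.character(testCopy(ed)), 2, 4), "ACT")
  expect_identical(homologousPositions(ed)[1:3], 2:4)

  # GAC occupying unit positions 2-4: edit position 4, C -> G
  cas2 <- unitCassette("TGAC")
  ed2 <- deleteUnitTriplet(cas2, "GAC")
  expect_identical(substr(as.character(testCopy(ed2)), 1, 4), "TGAG")
  expect_identical(substr(as.character(testCopy(ed2)), 1, 3), "TGA")

  # a unit without the target (in either orientation) is returned unchanged
  cas3 <- unitCassette("TTAG")
  ed3 <- deleteUnitTriplet(cas3, "GAC")
  expect_identical(as.character(testCopy(ed3)), as.character(testCopy(cas3)))
})

test_that("triplet deletion handles reverse-complement occurrences", {
  # GTC is the reverse complement of GAC and is pooled in the census,
  # so the editor must destroy it too
  cas <- unitCassette("GTCA")
  expect_identical(unname(tripletCounts(enumerateUnitTriplets(cas))["GAC"]), 1L)
  ed <- deleteUnitTriplet(cas, "GAC")
  expect_identical(unname(tripletCounts(enumerateUnitTriplets(ed))["GAC"]), 0L)
  # the unit's other overlapping triplet class survives
  expect_identical(unname(tripletCounts(enumerateUnitTriplets(ed))["TCA"]), 1L)
})

test_that("triplet deletion reduces only the target class in the census", {
  set.seed(21)
  for (i in 1:10) {
    ref <- randomReference(220, seed = 400 + i)
    cas <- generateTest(ref, HomologyPattern(4, 7, 1, 220), seed = i)
    before <- tripletCounts(enumerateUnitTriplets(cas))
    target <- "GAC"
    nTarget <- before[target]
    ed <- deleteUnitTriplet(cas, target)
    after <- tripletCounts(enumerateUnitTriplets(ed))
    nEdits <- if (is.null(ed@provenance$edits)) 0L
              else nrow(ed@provenance$edits)
    expect_identical(unname(before[target] - after[target]), nEdits)
    expect_identical(unname(nEdits), unname(nTarget))
    expect_identical(after[names(after) != target],
                     before[names(before) != target])
  }
})

test_that("first-n occurrence editing stops after n edits", {
  # two GAC-bearing units at positions 1-4 and 12-15
  ref <- "GACTAAAAAAAGACTAAAAAAA"
  cas <- generateTest(ref, HomologyPattern(4, 7, 1, 22), seed = 5)
  expect_identical(unname(tripletCounts(enumerateUnitTriplets(cas))["GAC"]), 2L)
  ed <- deleteUnitTriplet(cas, "GAC", occurrences = 1)
  expect_identical(unname(tripletCounts(enumerateUnitTriplets(ed))["GAC"]), 1L)
  # the edited occurrence is the first in sequence order
  expect_identical(substr(as.character(testCopy(ed)), 1, 1), "C")
})

test_that("composed cassettes reflect every component in mask and length", {
  ref <- randomReference(500, seed = 12)
  p <- HomologyPattern(4, 7, 1, 500)

  # interruption splits a 100-bp block into 38- and 40-bp homologous runs
  spec <- CassetteSpec(ref, p, blockLen = 100L, blockSide = "left",
                       interruption = c(39L, 22L))
  cas <- composeCassette(spec, seed = 9)
  expect_equal(length(homologyMask(cas)), 600)
  blockMask <- homologyMask(cas)[1:100]
  runs <- rle(blockMask)
  expect_identical(runs$lengths[runs$values], c(38L, 40L))

  # a junction insert is wholly non-homologous and adds its length
  spec2 <- CassetteSpec(ref, p, blockLen = 100L, blockSide = "left",
                        junctionInsertLen = 11L)
  cas2 <- composeCassette(spec2, seed = 9)
  expect_equal(length(homologyMask(cas2)), 611)
  expect_true(all(!homologyMask(cas2)[101:111]))
  expect_true(all(homologyMask(cas2)[1:100]))

  # degenerate composition equals plain generation
  spec3 <- CassetteSpec(ref, p)
  cas3 <- composeCassette(spec3, seed = 9)
  plain <- generateTest(ref, p, seed = RIPforge:::.childSeed(9, "region"))
  expect_identical(as.character(testCopy(cas3)), as.character(testCopy(plain)))

  # a 15-bp perfect block adds exactly 15 homologous positions
  spec4 <- CassetteSpec(ref, p, blockLen = 15L, blockSide = "right")
  cas4 <- composeCassette(spec4, seed = 9)
  expect_equal(sum(homologyMask(cas4)), sum(homologyMask(p)) + 15)
})

test_that("adding a block never perturbs the main region's sequence", {
  ref <- randomReference(500, seed = 13)
  p <- HomologyPattern(5, 6, 1, 500)
  bare <- composeCassette(CassetteSpec(ref, p), seed = 4)
  withBlock <- composeCassette(
    CassetteSpec(ref, p, blockLen = 100L, blockSide = "left"), seed = 4)
  expect_identical(substr(as.character(testCopy(withBlock)), 101, 600),
                   as.character(testCopy(bare)))
})

test_that("invalid compositions are rejected", {
  ref <- randomReference(100, seed = 1)
  expect_error(CassetteSpec(ref, blockLen = 50L, blockSide = "left",
                            interruption = c(40L, 20L)),
               "within the block")
  expect_error(CassetteSpec(ref, blockLen = 50L, blockSide = "none"),
               "if and only if")
})
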