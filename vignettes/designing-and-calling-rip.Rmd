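---
title: "Designing interspersed DNA homology and calling RIP mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing interspersed DNA homology and calling RIP mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RIPforge)
```

## The biological problem

During the sexual phase of the *Neurospora crassa* life cycle, haploid
germline nuclei scan their genome for duplicated DNA. Sequences recognized
as duplicated are subjected to repeat-induced point mutation (RIP):
cytosines within the duplicated regions are mutated to thymines, which is
observed in sequenced progeny (spores) as C&rarr;T changes on one strand
and G&rarr;A changes on the other. How two double-stranded DNA molecules
recognize each other as homologous — apparently without strand invasion or
the RecA machinery — is the open mechanistic question this experimental
system probes.

The assay works with an engineered repeat cassette: a fixed "left" copy
(the *reference*, an arbitrary genomic segment) and a designed "right" copy
(the *test*) whose agreement with the reference is under full experimental
control. After a cross, the cassette is re-sequenced from individual spores
and every C&rarr;T / G&rarr;A difference from the expected sequence is
counted. The mean number of mutations per spore measures how strongly the
designed homology triggered RIP.

RIPforge implements the computational machinery of this assay end to end:
pattern design, cassette composition, targeted triplet editing, triplet
censusing, mutation calling, per-site profiling, the statistical
comparisons, and a stochastic spore simulator so that the entire pipeline
runs and is testable with no external data.

## Interspersed homology patterns

A pattern of interspersed homology is written `XH-YN_Z`: homologous units
of **X** bp, separated by **Y** bp of designed non-homology, the first unit
starting at 1-based sequence position **Z** of an **L**-bp region. The
periodicity is **X + Y**. The homologous positions are exactly

$$\{\, Z + k(X+Y) + j \;:\; k \ge 0,\; 0 \le j < X \,\} \cap [1, L].$$

```{r pattern}
p <- HomologyPattern(4, 7, Z = 1, L = 550)
p
head(homologousPositions(p), 12)
```

Design choices here, made once and kept:

* **Coordinates are 1-based inclusive** in every interface (Z = 1 means the
  first base). BED exports convert to that format's 0-based half-open
  convention on write only.
* **No partial unit is placed before Z**: positions 1 .. Z−1 are
  non-homologous. Shifting Z by one full period therefore removes exactly
  the first unit and nothing else — a set identity the tests assert — and
  varying Z from 1 to X+Y changes the base-pair content of the units
  without changing the homology-block structure, which is the whole point
  of the Z parameter.
* **Ends truncate by default.** Units crossing the region end are clipped
  at L. The alternative `endPolicy = "extend"` lengthens the final unit by
  a stated number of positions; it exists because several historical
  constructs carried a last unit accidentally extended by 1–3 bp, and
  reproducing them requires representing that accident.

The designed test copy substitutes every non-homologous position of the
reference with one of the three alternative bases, chosen with equal
probability and independently of neighbors:

```{r generate}
set.seed(20)
ref <- paste(sample(c("A", "C", "G", "T"), 550, replace = TRUE),
             collapse = "")
cas <- generateTest(ref, p, seed = 1)
cas
percentIdentity(cas)
```

A 4H-7N pattern leaves 4 of every 11 positions identical, i.e. an overall
identity of 36% — the identity level at which interspersed homology alone
can still drive RIP. Forcing a *different* base (never resampling the same
one) makes the homology mask exactly equal to position-wise equality; the
`Cassette` class validates this invariant on construction, so no cassette
with an inconsistent mask can exist.

Randomness is reproducible: one top-level integer seed, with each cassette
component drawing from its own deterministically derived child stream.
Adding a block to a composition therefore never perturbs the 500-bp
region's sequence. The original generator's RNG is not reproducible, so
only distributional equivalence with historical constructs is claimed.

## Composing full cassettes

Real constructs combine the 500-bp patterned region with an adjacent block
of 0–100 bp of perfect (or again patterned) homology, optionally separated
by a random junction insert, and optionally with part of the block replaced
by non-homology:

```{r compose}
spec <- CassetteSpec(ref, p, blockLen = 100L, blockSide = "left",
                     interruption = c(39L, 22L))
composed <- composeCassette(spec, seed = 7)
composed
rle(homologyMask(composed)[1:100])
```

Replacing 22 bp in the middle of the 100-bp block splits it into
homologous runs of 38 and 40 bp. Junction inserts and interruption filler
are built so that the test base differs from the reference base at *every*
filler position. This is deliberately stronger than sampling random filler
and rejecting accidental matches: per-position mismatch leaves no residual
homology at all inside the filler, which keeps the non-homology contract
trivially auditable from the mask.

## Triplet censuses and targeted editing

Prior work implicated base-pair *triplets* as the elementary unit of
homology recognition. The census therefore enumerates the 3-bp words
contained in homologous units, pooling each word with its reverse
complement (no 3-mer is its own reverse complement, so there are exactly 32
classes). The canonical name is the lexicographically smaller orientation —
any fixed convention works; this one is stated for reproducibility.

```{r census}
head(censusTable(enumerateUnitTriplets(cas)))
```

Two counting decisions:

* Counting is over **maximal homologous runs** of the mask, not nominal
  units. For clean patterns these coincide (a 4-bp unit holds two
  overlapping triplets, a run of length $\ell \ge 3$ holds $\ell - 2$), but
  edits and accidental extensions can split or merge runs, and run-based
  counting keeps the mask the single source of truth.
* Runs shorter than 3 bp contribute nothing.

Deleting a triplet — e.g. asking whether GAC units are privileged — must
destroy the target without touching the unit's other overlapping triplet.
In a 4-bp unit each triplet owns exactly one private base: position 1 if
the triplet occupies positions 1–3, position 4 if it occupies 2–4.
Substituting that base with its complement removes the target (G&rarr;C for
a leading GAC, C&rarr;G for a trailing one), preserves the neighbor
triplet, and turns the edited position non-homologous:

```{r edit}
unitCas <- Cassette("GACTAAAAAAA", "GACTCCGCCGC")
as.character(testCopy(deleteUnitTriplet(unitCas, "GAC")))
```

The implementation generalizes the rule: the edited base is the one covered
by the fewest *other* triplet windows of the same run (zero for unit-edge
triplets). When every base of an occurrence is shared — possible in long
perfect runs — the least-shared base is edited anyway and a message is
logged, since the occurrence cannot be destroyed without collateral.
Reverse-complement occurrences (GTC on the given strand) are targeted by
the same rule, because the census pools both orientations and an editor
that ignored one of them would leave the pooled count wrong.

## Calling mutations and summarizing them

Calling compares a spore contig to its expected cassette sequence.
Positional mode (the default) compares site by site: RIP makes
substitutions only, so with clean Sanger contigs the sequences are
colinear. Mismatches classify as `CT` (expected C, observed T), `GA`
(expected G, observed A), or `other`; `other` calls are reported but
excluded from all RIP statistics, mirroring datasets that record only the
C/T and G/A totals.

```{r call}
calls <- callMutations("CCGG", "TCGA", sporeId = "SIMA1_1")
calls
```

Gapped mode exists for real contigs with sequencing artifacts. It aligns
globally (match 1, mismatch −2, gap opening −6, gap extension −1 — penalties
chosen to favor substitutions over gaps, as appropriate for a
substitution-only process), excludes gap columns from the counts with a
logged tally, and rejects alignments with more than 20% gap columns as a
likely wrong construct assignment. How the original analyses handled indel
artifacts is not recorded; gap-column exclusion is this package's choice.

Per-spore totals are summarized as mean ± SEM (sample SD over $\sqrt n$,
zero when $n = 1$), optionally restricted to a region such as the 500-bp
reference segment of a compound construct; region means are additive over
any split. Per-site profiles count, for each position, the spores mutated
there, expressed as percent of spores sequenced; C&rarr;T and G&rarr;A
calls are pooled per site, matching "number of mutations per site".

## Statistics

Replica crosses of one construct are compared by the two-sample two-sided
Kolmogorov–Smirnov test, and construct congruence is summarized by the
minimum pairwise p-value over all cross pairs, unadjusted (flagged in a log
when below 0.05, but no multiple-testing correction — the summary is
deliberately raw).

Mutation counts are small integers, so ties dominate and the KS variant
matters. `ksCompare()` evaluates D at the pooled observed values and
computes the exact p-value **conditionally on the observed tie pattern**
(when $nm \le 10{,}000$; asymptotic otherwise, with the method reported).
The conditional exact p equals brute-force enumeration over all
$\binom{n+m}{n}$ assignments of the pooled values — the package's tests
assert this identity directly. A consequence worth knowing: tie-blind
p-values (the asymptotic formula, or exact methods that assume continuity)
are systematically conservative on tied integer data and can differ from
the conditional exact value by more than 0.2; the two approaches agree
closely only when ties are absent.

Base-pair-level comparison of two constructs' profiles uses the Pearson
correlation of per-site counts over a stated region (at least 3 sites;
zero-variance profiles yield a flagged `NA` rather than an error). Pearson
r is scale-invariant, so counts and percents give the same answer and
profiles with different spore numbers are directly comparable.

## The spore simulator

The simulator exists so the caller, profiler and statistics can be
validated against planted ground truth. It is phenomenological, not
mechanistic — it does **not** map homology features to mutation intensity;
per-construct intensities are inputs:

* each spore escapes RIP entirely with probability `escapeProb`
  (real crosses contain a visible fraction of unmutated spores);
* a non-escaping spore draws Poisson(`lambdaMean`) mutations, each
  C&rarr;T with probability `ctGaRatio` (default 0.5), else G&rarr;A;
* mutations are placed without replacement among the class's mutable sites
  (reference C's, respectively G's), with probabilities proportional to a
  spatial weight profile. The default profile is a symmetric triangle
  peaking at the sequence center — mutations in real constructs concentrate
  symmetrically around the middle of the compound repeat;
* `indelRate` (default 0) deletes positions after mutagenesis, solely to
  exercise gapped calling.

```{r simulate}
casSim <- generateTest(ref, perfectPattern(550), seed = 1)
sim <- simulateSpores(casSim, RipSimModel(lambdaMean = 10), nSpores = 30,
                      seed = 11, construct = "SIMA")
recalled <- lapply(seq_along(sim$spores), function(i)
  callMutations(referenceCopy(casSim), sim$spores[[i]],
                sporeId = names(sim$spores)[i]))
unlist(meanMutations(recalled))
```

With zero indel rate, calling recovers the planted mutation lists exactly
(position by position), per-spore means recover
$\lambda (1 - \text{escapeProb})$ within sampling error, and the
normalized site profile tracks the spatial weights. `emulateStudy()` wraps
this into a full dataset — a 4-field contig CSV
(`id,n_CT,n_GA,sequence`, identifiers `{RepeatID}{cross}_{spore}`),
expected-cassette FASTAs, a construct table and a planted-truth TSV — whose
recorded counts must round-trip through the caller, and does so
byte-identically under a fixed seed. The bundled intensity table
(`studyManifest()`) is labeled illustrative: synthetic RepeatIDs, values
merely shaped like the observed spread across constructs (near-silent to
~10 mutations per spore).

What the simulator deliberately omits — and hence what passing tests do
*not* establish about real data: RIP's CpA dinucleotide context
preference; processivity and clustering of mutations along a molecule;
overdispersion or bimodality of per-spore counts (real count distributions
are not well characterized; Poisson-plus-escape is an assumption to
revisit); any coupling between homology pattern and intensity; and
sequencing error. The simulator validates the *bookkeeping* of the
pipeline, not the biology.

## Numerical and testing choices

* Triplet canonicalization, mask derivation and filler construction are
  exact integer/character operations; there are no tolerances in the
  sequence layer.
* KS p-values are compared to enumeration at $10^{-10}$; enumeration is
  restricted to $n + m \le 12$ where it is cheap and exhaustive.
* The test suite sizes its simulations to keep the full run around half a
  minute on one core: 300–1000 random patterns against the enumeration
  oracle, 40–200 random cassettes against the window-scanning census
  oracle, 50 seeds of simulate-then-call exactness on 8-spore batches, and
  single larger draws (500–1000 spores) for distributional recovery. These
  sizes are comfortable for the properties asserted; nothing in the
  assertions depends on the sizes beyond ordinary sampling error, and the
  fixed seeds make every run identical.
* The editor resolves occurrences against the *original* census, then
  applies all edits at once; duplicate edit positions (overlapping
  occurrences) collapse to a single substitution.

## Known limitations

* The ClustalW reader is permissive about dialect but expects the standard
  two-blank-line header; unusual writers may need pre-normalization.
* Gapped calling reports positions in expected-sequence coordinates;
  insertions in the spore have no expected coordinate and are dropped with
  the gap-column log, so downstream per-site profiles are blind to them.
* `verifyRecordedCounts()` routes spores by the alphabetic prefix of their
  identifier; identifiers whose RepeatID contains digits are rejected
  rather than guessed at.
* Restriction sites (NotI/NdeI) are treated purely as positional markers;
  no cloning simulation is attempted, and no genome-scale repeat discovery
  is in scope.
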