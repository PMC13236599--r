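---
title: "Detecting latent giant viruses in algal genomes: models and methods"
author: "evetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latent giant viruses in algal genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evetrace)
```

## The biological system

Brown algae of the genus *Ectocarpus* carry enormous (roughly 288--407 kb)
phaeoviral genomes integrated into their chromosomes as endogenous viral
elements (EVEs). These proviruses are hemizygous — present on only one of
the two homologous chromosomes of the diploid — and mostly silent, but
under inducing conditions an active element excises, replicates, and
produces virions, with symptoms transmitted vertically through meiosis
like a Mendelian locus. Four genomic signatures characterize this life
cycle, and `evetrace` implements a detector for each:

1. **Integration junctions.** A tyrosine recombinase integrates the
   circular viral genome at a host attachment site (attB) through a
   minimal shared core — a `CC` dinucleotide, with weakly conserved
   `ATA` context — creating two host--virus junctions, attL and attR.
   Because host and virus share the core, the exact breakpoint is
   ambiguous within the microhomology.
2. **Attachment-site architecture.** The viral attP site carries the
   core flanked by AT-rich inverted repeats; EVE left ends carry a
   conserved inverted repeat and right ends imperfect direct repeats.
3. **Excision, replication and hairpin telomeres.** On activation,
   recombination between attL and attR releases a circle (long reads
   spanning the re-formed attP), copy number rises over the locus, and a
   telomere resolvase can linearize the circle at a palindromic telRL
   site, leaving covalently closed hairpin ends that sequence as
   fold-back (sense-then-antisense) reads with a staggered apex loop.
4. **Mendelian genetics.** A hemizygous active element is transmitted to
   half the haploid meiotic progeny; symptoms co-segregate with it.

No external data are required: a synthetic-data module generates hosts,
elements, molecule classes, long reads and progeny with ground truth, so
every detector is tested against known coordinates.

## The synthetic-data generator

`make_eve()` emits an element in its integrated orientation with, by
default: length 30 kb (a deliberate scale-down of the real 288--407 kb
elements that preserves every junction-level feature at desk-scale
runtimes), GC 0.52 (the observed EVE composition), a 2-bp `CC` attP
core as its final bases, 12-bp AT-rich attachment arms (AT fraction
0.8), a left-terminal inverted repeat (10-bp arms, 8-bp loop),
imperfect direct repeats near the right end (15-bp unit, 1 mismatch),
and a telRL block at half the element length: 15-bp perfect
inverted-repeat arms around a 6-bp palindromic core (`TTCGAA`),
separated by short non-complementary spacers. Optionally an IS4-family
transposon (2 kb) is inserted with an 8-nt target-site duplication.

Three construction details matter for interpreting results:

* **Junction-base guards.** The generator fixes the last base before
  the viral core to `C` and the planted attB context to `ATACC`
  followed by `A`, so the host--virus microhomology is exactly the core
  and never extends by chance. Likewise the transposon's terminal bases
  are adjusted so the duplication is exactly 8 nt. Without these guards
  a worked example would be correct-but-off-by-one in a seed-dependent
  way; with them, core length 2 and TSD length 8 are deterministic
  properties of the model rather than of a lucky seed.
* **telRL spacers.** The outer inverted-repeat arms do not abut the
  core: if they did, arm + palindromic core + arm would itself be one
  long palindrome and "a 6-bp palindrome within a larger inverted
  repeat" would be ill-defined. The 3-bp spacers (`ACG`) block
  palindrome extension, so the 6-bp core is the maximal even palindrome
  at its center while the 15-bp arms still form the larger repeat.
* **Apex content.** The hairpin loop is taken as the central
  `stagger_nt` bases of the telRL core's top strand. Whether a real
  hairpin apex derives from one or both strands is not observable from
  the fold-back signature itself (and for a palindromic core the two
  choices coincide); this is a modelling choice, not an inference.

What the generator does **not** emulate: realistic long-read error
profiles (substitutions only, no indels or homopolymer artifacts),
basecalling, diploid SNP background beyond the presence/absence
difference, or nested insertions. Passing tests therefore demonstrate
correctness of the algorithms under the stated error model, not
end-to-end performance on raw nanopore data.

## Junction resolution

`anchor_map()` enumerates all maximal exact matches of length at least
`k` (default 15) between two sequences on both strands — k-mer hits
collapsed along diagonals are exactly the maximal matches — and chains
them colinearly by dynamic programming, allowing adjacent anchors to
overlap by up to `k - 1` bp because junction microhomology duplicates
sequence between the flanks. A quadratic diagonal-scan oracle verifies
the enumeration in the test suite.

`resolve_insertion()` merges the chain into colinear blocks (gaps up to
`gap_tol` = 30 bp in both coordinates bridge substitution noise) and
reports each block gap that is long on the EVE-bearing haplotype but
absent on the homolog. When the flanking blocks overlap on the homolog,
that overlap is the microhomology; the insert is reported
**leftmost-canonical** on the forward strand (the VCF-style convention;
the truth generator records the same convention so exact comparison is
meaningful). When a flank block is fragmented — the signature of
substitution noise, since a clean flank is a single maximal match
reaching the junction — the breakpoint is refined base-by-base with a
log-likelihood-ratio walk (match: +1.37, mismatch: -3.6, the log odds
of "inside the flank" at 2% error versus "past the junction" at 25%
chance matching), taking the leftmost score maximum. Refinement is
deliberately *disabled* for clean flanks: on error-free input the
maximal-match end already is the junction, and extending past it could
only chase chance matches.

`classify_mechanism()` separates the two integration chemistries by the
structure of the shared sequence: a duplication of at least 4 bp is a
transposase target-site duplication (`dde_tsd`); a shorter shared
string (1--10 bp) is a recombinase core (`recombinase_core`) if
rotating the leftmost-canonical insert by the microhomology length
reconstructs the element — equivalently, the insert is a rotation of
the circular genome, which is precisely the recombinase model. The 4-bp
and 10-bp thresholds are package choices (no published boundary
exists); they guarantee a 2-bp core is never miscalled as a TSD.
`extract_att_quartet()` then cuts attB/attL/attR around the core and
forms attP by joining the element's right terminus to its left across
one core copy — the same string produced by excising the circle, which
the tests assert.

## Terminus profiles and attachment-site consensus

The published screen built profile HMMs from trimmed terminus
alignments and scanned assemblies with them. `evetrace` implements the
same pipeline with **ungapped position log-odds profiles**: per-column
counts with pseudocount `alpha = 1`, log-odds against a background that
defaults to the scanned contig's own composition, and a sliding-window
scan of both strands that provably equals exhaustive window scoring
(oracle-tested). Gapped HMM scoring is an extension point; the
downstream filters transfer unchanged. Hits must be at least 80 bp long
and intersect the model within 50 bp of its terminal column (both
bounds inclusive — "at least" and "within" read naturally as closed
bounds); truncated model windows at contig edges supply the nonzero
`dist_to_model_end` values. `dedup_flanks()` collapses hits with
string-identical 100-bp flanking host sequence (the width is a package
default; the source procedure specifies "identical flanking sequences"
without one). "Within 50 bp" is interpreted in model coordinates; the
contig-coordinate alternative can be obtained by filtering on hit
coordinates directly.

`make_logo()` reports per-column frequencies and information content
`IC = 2 - H` bits with no small-sample correction (WebLogo applies
one; the difference is irrelevant at the simulated set sizes but is a
recorded divergence). `infer_att_consensus()` aligns attL and attR sets
on their junctions and takes the maximal run of agreeing pre-junction
consensus columns as core-plus-extended-homology; with the default
generator this recovers `CC` with near-2-bit columns, and planting the
`ATA` context on only the host side correctly does *not* extend the
called core.

## Excision signatures from long reads

All three detectors run on anchor tables computed once per read against
the integrated reference (or the circle):

* **attP-spanning reads** (`detect_attP_spanning()`): two same-strand
  anchors adjacent in the read (gap at most 50 bp, overlap at most
  20 bp) jumping from within 500 bp of the EVE right terminus to within
  500 bp of the left terminus.
* **Fold-back reads** (`detect_foldback()`): a sense and an antisense
  anchor block (each at least `min_arm` = 100 bp) whose reference
  footprints overlap by at least half the shorter arm — the overlap
  requirement separates hairpin ends from inter-locus chimeras. The
  reversion coordinate is the midpoint of the two blocks' innermost
  *read* edges projected through the sense anchor onto the reference.
  For a hairpin with a palindromic apex, both anchor blocks extend
  through the apex on the reference, so a reference-edge midpoint would
  sit at the apex *end* (a bias of half the stagger); the read-edge
  projection is exact for error-free reads and unbiased in general,
  which the 1000-read estimator test verifies.
* **Coverage enrichment** (`coverage_ratio()`): median chained-anchor
  depth inside the EVE interval over the median outside. The reference
  is haploid (the gametophyte case); under a diploid interpretation the
  hemizygous baseline halves and thresholds should be scaled
  accordingly.

`cluster_reversions()` single-links reversion coordinates (radius
10 bp) and takes the largest cluster's median; `locate_telrl()` then
searches ±50 bp for the even palindrome (length 4--12) whose center is
nearest the consensus, ties broken leftmost, and annotates the
surrounding inverted repeat. `summarize_excision()` raises the
circularization / linearization / replication flags at 3 supporting
reads each and a coverage ratio of 2 — desk-scale defaults chosen for
the simulated depths; no published thresholds exist. The fold-back
signature itself cannot distinguish covalently closed telomeres from
replication intermediates, and the detectors make no claim about which
molecular form is packaged; they report the signature only.

## Segregation and linkage statistics

`simulate_cross()` transmits each chromosome homolog with probability
1/2 independently, which yields all the observed genetics: unlinked
hemizygous loci segregate 1:1, two loci on different homologues of one
chromosome are mutually exclusive (exactly one inherited — the
EVEh/EVEi configuration, under which every progeny carries at least one
element), and fully linked loci co-segregate. Symptoms arise in
carriers of an active locus with probability `penetrance`; penetrance
is this package's modelling addition to reconcile sub-100% symptomatic
fractions among obligate carriers with full linkage, and is estimated
by `estimate_penetrance()` with a Wilson score interval.

`linkage_test()` is the Pearson chi-square on the 2x2
presence-by-phenotype table with Yates continuity correction on by
default (matching the common statistical-environment default for 2x2
tables, and verified against `stats::chisq.test()` in the tests);
`mendelian_test()` is the goodness-of-fit chi-square against an
expected ratio. On 46 symptomatic versus 65 asymptomatic progeny
against 1:1 the statistic is 3.252 and p = 0.0713 — the worked
segregation example reproduced in the tests. Published linkage
p-values from partially genotyped progeny subsets are not asserted:
the underlying subset counts are not available, so no exact match is
possible. `relative_copy_number()` implements the delta-Cq formula
`2^(Cq_ref - Cq_target)`.

One statistical subtlety is handled explicitly: the claim "the Wilson
interval covers penetrance 0.9 in at least 95% of simulations" has a
true per-simulation probability of 0.9506 under the cross design
(computed exactly by binomial summation, mixing over the carrier count)
— essentially *equal* to the 95% threshold, so a Monte-Carlo fraction
over 1000 seeds lands on either side of it by chance. The tests
therefore assert the exact coverage (deterministically at least 0.95)
plus consistency of the simulated fraction with that exact value within
three binomial standard errors, rather than a coin-flip literal bound.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; BED output
  keeps that convention, GFF3 output converts to 1-based inclusive.
* `k = 15` anchor seeds; flanks need 30 bp of anchor support per side;
  breakpoints leftmost-canonical; ties in palindrome search leftmost.
* Circle mapping is handled by doubling the circle string, not by
  circular coordinates.
* Error model: uniform substitutions only (default rate 0, at most
  0.2); indels are out of scope.
* Degenerate inputs: identical haplotypes resolve to an *empty* result
  (not an error); a large unexplained length difference with no
  flanking anchors is a resolution error; zero-margin 2x2 tables and
  zero-carrier penetrance calls are contract errors.
* Problem sizes in the test and acceptance runs — 30-kb default
  elements (2.5--8 kb in bulk property loops), 2000 replicate crosses
  of 200 progeny, 60x hairpin depth, 20 + 20 symptomatic/asymptomatic
  screens — are the package's desk-scale study conditions; they
  exercise every feature of the full-scale system at a fraction of the
  sequence length.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- default_config(seed = 5)
res <- run_pipeline(cfg, out_dir = "evetrace-demo")
res$junctions       # recombinase_core junction, core CC, 2 bp
res$excision        # circularization / linearization / replication flags
res$linkage         # chi-square linkage of the active locus
```

The package functions, this vignette and `scripts/acceptance.R` are the
interface; each stage is equally callable on real FASTA/FASTQ input via
`read_fasta()` / `read_fastq()`.

## Known limitations

* The profile scanner is ungapped; strongly indel-diverged termini
  would need the HMM extension.
* No nested insertions (an EVE inside an EVE) and no whole-genome SV
  calling: the resolver expects haplotype pairs that are colinear
  outside the insertions.
* The read simulator's error model is substitution-only, and detection
  guarantees are stated under that model.
* Linkage analysis is single-hypothesis by design (one active locus
  tested at a time); no multiple-testing correction across loci.
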