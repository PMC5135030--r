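---
title: "Detecting and characterizing giant-ankyrin long exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing giant-ankyrin long exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giantexon)
```

## The problem

Canonical ankyrins couple membrane proteins to the spectrin cytoskeleton
through 24 ankyrin repeats, a ZU5–ZU5–UPA cassette, and a death domain (DD).
Giant ankyrin isoforms — vertebrate 480-kD AnkG, fly Ank2-L/XL, and their
relatives — add a multi-kilobase polypeptide encoded by a single unusually
long exon near the DD, and build the proximal-axon diffusion barrier and the
axon initial segment. Testing whether such exons are ancestral to
bilaterians requires a chain of quantitative analyses: placing a candidate
exon within its genome's ORF-length distribution, searching annotated loci
for long stop-free ORFs, comparing amino-acid composition, separating true
from chance alignment similarity, finding internal repeat arrays, and
quantifying diffusion-barrier function by FRAP. This vignette documents how
each procedure is defined here, the tunable parameters, the simulation model
behind the tests, and the limits of both.

## ORF scanning and ranking

`find_orfs()` enumerates maximal stop-free codon runs in all six frames. An
ORF is *not* required to start with ATG: the object of interest is
uninterrupted coding capacity, so the unit is a run of sense codons bounded
by stop codons, contig ends, or codons containing `N` (we terminate runs at
ambiguous codons — the conservative choice, since an `N` codon cannot be
certified stop-free). The default threshold is strict (`length_nt > 300`,
i.e. ≥ 303 nt after codon rounding), with `strict = FALSE` exposing the
inclusive variant. The bounding stop codon is not counted in the length.

`filter_simple_repeats()` removes ORFs that owe their length to
low-complexity sequence. A position is masked when it lies inside an exact
tandem run of any motif of ≤ 6 nt spanning ≥ 50 nt (detected as period-*m*
self-matches), and ORFs more than 50% masked are dropped. No published
parameterization exists for this filter, so all three thresholds are
arguments; the defaults are ordinary choices for separating microsatellite
runs from coding sequence.

`summarize_lengths()` reports the census size, mean, and standard deviation
(population SD by default — genome censuses are complete enumerations, not
samples; `sd_type = "sample"` switches the divisor) plus a 250-bp histogram
of the top 1,000 ORFs. `rank_query()` uses minimum rank (1 + the number of
strictly longer ORFs) and the z-score $(q - \mu)/\sigma$. As a worked
arithmetic check, a 13,344-nt exon against a census with
$\mu = 436, \sigma = 308$ bp gives $z = 41.9 \approx 42$.

## Long-exon search at a locus

`scan_locus()` encodes the locus-level search rule: starting at the 3′ end
of the last UPA-mapped exon, scan to the start of the adjacent downstream
gene (or the contig end if none is annotated), on the locus strand only —
a giant exon must be readable in the gene's orientation. Candidate calls are
ORFs above 3 kb; a locus with no ORF above 1 kb in the window receives an
absence certificate, the criterion by which cnidarian-style loci are scored
as unable to encode giant isoforms. The window deliberately spans the
introns between UPA and DD *and* the region beyond the DD, because both
placements occur in nature (chordates upstream of the DD; protostomes and
echinoderms downstream).

Position relative to the DD is classified by comparing the call's midpoint
to the DD exon span, in the transcription sense; a call overlapping the DD
span is reported upstream with a warning, and loci without a mapped DD
(the lancelet situation) yield `DD_absent`. Calls overlapping annotated
exons of the input prediction are discarded — the search target is novel
coding capacity between annotated features. Gene predictions are taken as
given: no attempt is made to repair or re-annotate them, since no principled
adjustment rule is available. `classify_exon_count()` distinguishes none /
single / tandem (≥ 2 passing calls, the fly L + XL configuration).

## Composition and enrichment

`aa_frequencies()` reports percent composition over the 20 standard
residues; ambiguity codes (X, B, Z, U, J, O) are excluded from numerator and
denominator, with the excluded count reported. `average_profiles()` takes
the *unweighted per-sequence mean* — each polypeptide counts equally
regardless of length, matching how an "average composition over N
sequences" is ordinarily formed; residue-pooled weighting is available via
`weights = "residues"`. `top_k_fraction()` orders residues by descending
frequency (ties alphabetical). `codon_fraction()` is the null reference:
the fraction of the 61 sense codons of the standard genetic code encoding a
residue set — 20/61 = 32.8% for {S, E, T, D, K, P}. `fold_enrichment()`
divides averaged long-exon by averaged core frequencies elementwise,
flagging zero-denominator residues as undefined rather than infinite.
`composition_matrix()` lays sequences × residues out with residues in
ascending mean frequency, ties alphabetical.

## Homology blocks and the shuffled null

The discriminating statistic is the partition of aligned identities into
singlets versus blocks: `block_partition()` takes maximal runs of
consecutive identical columns (any gap or mismatch breaks a run) and reports
the percent of identities in runs of length 1 and in runs ≥ 4. Genuine
homology concentrates identities into blocks; alignments against shuffled
sequences scatter them almost entirely as singlets.

`global_align()` provides the underlying alignment: Needleman–Wunsch with
affine gaps (Gotoh's three-state recursion, compiled), end gaps penalized,
gap cost `open + L × extend`, and a fixed tie-break order (diagonal, then
gap in the second sequence, then gap in the first) so results are
deterministic. Robustness to aligner choice is probed by a documented grid
of six (matrix, gap-open, gap-extend) settings spanning the BLOSUM and PAM
series (`default_aligner_settings()`); identity is reported as mean ± SEM
over the grid. The default percent-identity denominator is alignment columns
excluding terminal gap overhangs; shorter-sequence and all-columns
denominators are flags, since conventions differ across the literature.

`shuffle_null()` aligns the first sequence against seeded Fisher–Yates
permutations of the second (composition preserved exactly; 20 shuffles per
setting by default) and compares real and null per-setting identities by a
two-sided two-sample t-test at α = 0.05. Self-comparison is always
significant; independent random sequences are not, in the large majority of
seeds — both properties are exercised in the tests.

## MSA conservation statistics

`column_identity_counts()` scores each column by the size of its largest
identical-residue class, with gaps never counting as matches (an all-gap
column scores 0); this yields "identical in all *n*" and "identical in
*m* of *n*" counts directly. `pairwise_identity_matrix()` computes identity
per pair over columns where neither row is gapped — the denominator that
reproduces conventional core-domain identity figures — with an all-columns
variant behind a flag.

## Tandem-repeat arrays

`detect_repeats()` finds periodicity by self-comparison: for each candidate
period *p* (10–300 by default), positions matching themselves at lag *p* are
found, a trailing window of *p* lags is required to stay above the identity
threshold (70%), passing stretches become candidate arrays, and candidates
from different periods are merged by keeping the highest score
(copies × identity), which also resolves harmonics — a true period *p*
echoes at 2*p* with half the copy number and therefore loses. Arrays report
unit length, copy number (span/period, rounded), span, and mean consecutive-
unit identity. Defaults (≥ 5 copies, units 10–300 residues or nt) bracket
the ranges reported for ankyrin long-exon arrays (5 to > 160 copies, 36–228
bp units). The detector assumes substitution-style divergence between
copies; arrays diverged by indels shift the register between units and are
outside its design (an alignment-based refinement would be needed), and unit
boundaries are recovered only up to rotation and ± a few positions of flank
absorption — hence the ± one-unit tolerance used in the tests.

## FRAP and intensity profiles

`normalize_frap()` implements double normalization: the bleached-region
signal is divided by the unbleached reference region (correcting whole-cell
acquisition bleaching), that ratio is divided by its pre-bleach mean (all
pre-bleach samples are used for the baseline), and the result is mapped to
percent recovery with the first post-bleach sample at 0% and the pre-bleach
level at 100%. A ratio that never drops (`r(t0+) = 1`) is rejected as "no
bleach depth", as is any non-positive reference. A width-3 median filter for
vesicle-transit blips is available but off by default. The procedure is
invariant to rescaling both channels by a common factor.

`recovery_plateau()` averages normalized recovery over 110–120 s. (Source
figure captions alternate between "110 and 120 ms" and "seconds" for the
same quantification; seconds is adopted, since the time courses run about
two minutes.) `compare_plateaus()` is a two-sided Welch t-test on per-cell
plateaus, reporting p = 1 (or 0) instead of erroring when both groups are
degenerate-constant. `normalize_profile()` applies the two-step line-profile
normalization — divide by the mean of the lowest 25% of values, then by the
mean of the highest 5% of the result — with window sizes taken over sample
counts (ceiling, minimum one sample); the transform is monotone, so peak
location and ordering are preserved.

## What the simulators emulate — and what they do not

Every generator draws from its own RNG stream derived from (seed, kind), so
fixtures are bit-reproducible and adding a generator never perturbs another,
and each returns a truth record consumed by the tests.

* `gen_genome()` draws codons i.i.d. (stop probability `stop_density`, else
  uniform sense codon), giving frame-0 forward ORF lengths an exactly
  geometric tail with mean ≈ 3/`stop_density` nt; planted intervals are
  stop-free and stop-bounded so the scanner must recover them exactly. Real
  genomes add GC skew, repeats, and codon-usage structure that this model
  does not attempt.
* `gen_locus()` builds the four diagnostic architectures (no long exon;
  long exon between UPA and DD; after the DD; tandem pair after the DD) over
  a stop-dense background (`stop_density` 0.05, keeping background ORFs far
  below 1 kb), on either strand. Exon sizes (150 nt) and intron sizes
  (300–900 nt) are ordinary invertebrate-scale values; the scan logic does
  not depend on them.
* `gen_protein_pair()` controls both the identity level and its arrangement
  (blocks ≥ 4 vs isolated singlets), separating what the block statistic
  must separate. Real homologs also drift in length; the simulator keeps
  lengths equal, so gap placement is exercised by the aligner tests rather
  than the pair generator.
* `gen_biased_polypeptide()` draws residues i.i.d. from a target vector
  (default `long_exon_bias_target()`: S + E = 25%, top six = 56%);
  multinomial sampling gives the 3-SE convergence bound used in tests.
* `gen_repeat_array()` mutates tandem copies by substitution only (see the
  detector's indel caveat above).
* `gen_frap_trace()` uses single-exponential recovery
  $r(t) = r_0 + (1 - r_0)\,m\,(1 - e^{-t'/\tau})$ in ratio space, plus a
  slow shared acquisition-bleach decay and independent 1%-CV channel noise.
  Defaults (130 s movie at 2 Hz, bleach at 5 s, depth 0.7) put the 110–120 s
  window ≈ 3.5τ after the bleach for the slowest simulated τ of 30 s, where
  the closed-form window mean sits within 2.7 points of the asymptote —
  which is why parameter-recovery checks average plateaus over 10 simulated
  cells per condition, as the real procedure averages 13–25 cells per group.
  Real FRAP adds diffusion-geometry corrections and reactive binding that a
  single exponential does not model.
* `gen_msa()` builds columns with an exact largest-agreement class per
  requested conservation level; random filler columns can only add
  agreement, so specified counts are lower bounds.

Passing tests on these inputs demonstrate that each procedure measures what
it claims under its own model assumptions — not that the assumptions hold
for any particular genome or microscope.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally and in BED output, 1-based in
printed reports. Empty ORF sets summarize to `n = 0` with `NA` moments;
rank z-scores require σ > 0. Zero-identity alignments report `NA` singlet
and block percentages. Zero core frequencies yield flagged `NA` enrichment.
Zero-variance plateau groups report p ∈ {0, 1} by mean equality. Profile
normalization rejects a zero bottom-quartile mean; FRAP normalization
rejects zero bleach depth. The t-tests everywhere are Welch (unequal
variance) tests. Test-suite problem sizes (100-kb oracle genomes, 200
simulated loci, 300-mer protein pairs, 10 cells per FRAP condition) were
chosen as the smallest sizes at which the statistical claims have
comfortable margins.

## Known limitations

Splice-aware ORF assembly, gene prediction, domain annotation (ankyrin
repeat / ZU5 / UPA / DD detection), alignment construction for MSAs, and
phylogenetic inference are out of scope: domain-to-exon maps and alignments
are inputs. The aligner grid stands in for external alignment software — it
probes parameter robustness, not aligner diversity, and is not a bit-level
reproduction of any external tool. Repeat counts for real long exons depend
strongly on identity cutoffs; `detect_repeats()` reports its thresholds and
they should be stated alongside any count. Genome-scale censuses (e.g. the
81,915-ORF tunicate figure) require the corresponding genome assemblies and
are not reproduced by the desk-scale test suite.
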