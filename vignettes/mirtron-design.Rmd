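---
title: "Designing artificial mirtrons for knockdown-replacement constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial mirtrons for knockdown-replacement constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtronkr)
```

## The design problem

A mirtron is an intron whose spliced, debranched lariat folds directly into
a pre-miRNA hairpin: the 5' splice donor is the first base of the hairpin's
5' arm and the 3' splice acceptor the last base of its 3' arm. An
*artificial* mirtron carries a designed guide strand against a gene of
interest on one arm. Because splicing defines the mature RNA ends, the
design space is doubly constrained:

* the intron must begin `GT` and end `AG`, so a guide placed on the 5' arm
  must itself start `GT` (its first six bases *are* the donor), and a guide
  on the 3' arm must end `AG` with a usable polypyrimidine tract (PPT)
  immediately upstream;
* the hairpin must still look like a Dicer substrate with the right strand
  asymmetry so that the guide, not the passenger, loads into RISC.

For knockdown-replacement (KR) therapy the mirtron is additionally nested
inside an RNAi-resistant copy of the very gene it silences, which brings in
splice-signal strength of the host junction, exonic splice enhancers (ESEs),
first-exon length, and the risk of recoding accidentally creating new splice
signals. `mirtronkr` models each of these steps with small, transparent,
deterministic scores.

## Conventions

All sequences are DNA strings over `A/C/G/T` (`U` on input is normalised to
`T`; RNA lettering is display-only via `as_rna_display()`). All coordinates
are 1-based and inclusive, matching how positions are quoted in the
splicing literature ("a G-run at position 15" is the fifteenth intron base);
this is also the native convention of R and of Biostrings, which backs all
parsing and matching. `N` is rejected in design inputs and tolerated in
sequencing reads.

## Target scanning and scoring

`scan_targets()` enumerates, on the sense mRNA only (RNAi acts on the
mRNA), every window of the configured guide length (default 21 nt,
configurable 19–23) whose reverse complement satisfies an arm rule:
windows ending `AC` give 5'-arm guides (guide starts `GT`), windows
starting `CT` give 3'-arm guides (guide ends `AG`).

`score_targets()` combines three criteria into a composite with explicit
weights (defaults 0.4 / 0.4 / 0.2):

* **donor consensus** — for 5'-arm guides, the match of the guide's first
  six bases to `GTAAGT`, as `(6 − mismatches)/6`. For 3'-arm guides the
  donor lies on the freely designable passenger arm, so the component is a
  neutral 1.
* **PPT purity** — for 3'-arm guides, `1 − purines/10` over the 10 nt
  immediately 5' of the guide's terminal `NAG`. For 5'-arm guides the tract
  is carried by the editable passenger: neutral 1.
* **end bias** — a proxy for achievable RISC-loading asymmetry: the G/C
  enrichment of the guide's 3'-terminal four bases over its 5'-terminal
  four, rescaled to [0, 1].

The published screening algorithm behind this class of designs is not
printed anywhere in full, so the composite here is a documented
re-derivation of its stated criteria, not a bit-level reproduction; the
weights are configuration, recorded in every report. Specificity screening
is an exhaustive exact / k-mismatch / seed-complement (guide positions 2–8,
the standard seed convention) count over a supplied transcriptome — a
deliberate replacement of heuristic BLAST search with something exact and
reproducible at transcriptome scale.

## Hairpin assembly and passenger editing

`build_hairpin()` assembles `arm5 + loop + arm3` with the passenger
initialised as the guide's full reverse complement and then edited by
`design_passenger()`:

1. the splice terminus carried by the passenger is enforced (`AG` end for
   5'-arm guides, `GT` start for 3'-arm guides), accepting a terminal
   mismatch where the complement disagrees — terminal mismatches are normal
   in natural mirtron hairpins;
2. for 5'-arm guides, purines inside the 10-nt pre-acceptor window are
   converted to `T` (U-rich tracts are the strongest PPTs) wherever the
   resulting non-Watson-Crick pair is allowed;
3. the guide's 3'-terminal four positions are kept Watson–Crick paired, the
   smallest window that meaningfully biases RISC loading toward the guide.
   For 3'-arm guides rule 1 and rule 3 collide at the very last base (the
   acceptor `G` cannot WC-pair the forced donor `G`); the conflict is
   resolved in favour of splicing and reported as a warning, never
   silently.

The default backbone uses the widely used miR-30-style loop
(`TAGTGAAGCCACAGATGTA`) as a synthetic, configurable stand-in — the loop is
a parameter of `backbone_spec()`, and published mirtron backbones can be
dropped in directly. The packaged mirt-1cN-like fixture
(`mirt1cN_synthetic()`) is likewise a synthetic reconstruction constrained
by reported sequence features (donor `GTGAGA`, a G-quadruplet at intron
position 15, PPT `GTTCTTCTTT`, terminal `CAG`), not a transcription of an
unpublished figure sequence; it is intended for examples and tests only.

## Thermodynamics

`pairing_delta_g()` estimates hairpin free energy over the *designed*
pairing layout rather than predicting a minimum-free-energy structure: the
layout is engineered and fixed, and a deterministic, dependency-free score
is what variant ranking needs. Watson–Crick stacks use a Turner-style
nearest-neighbor table (kcal/mol, 37 °C); any stack containing a G–U wobble
contributes a flat −0.5; each mismatch adds +0.8 and interrupts stacking;
a constant +5.6 closes the hairpin loop. Under these rules adding a WC pair
can never raise ΔG and converting a WC pair to a mismatch always does,
which is exactly the monotonicity `destabilize()` exploits: it breaks WC
pairs by passenger-only substitutions (setting the passenger base equal to
its guide partner, which can never create a G–U), avoiding splice termini,
the protected guide 3' block and the PPT window, choosing positions
greedily by free-energy gain.

The estimator is sanity-checked against RNAfold (ViennaRNA) on a
20-hairpin random panel: the two agree in sign everywhere and rank-correlate
strongly (Spearman ≈ 0.96 on the fixed test panel; the test asserts > 0.8).
Absolute values are *not* comparable — the estimator scores a forced
layout, RNAfold a free fold — and are not asserted.

## Insertion sites and splice products

`find_insertion_sites()` treats every junction whose upstream exon ends
`AG` as a candidate and scores: similarity of the five flanking bases to
the favoured exonic context `CAAG|G` (0.5), ESE hexamer support (0.2,
saturating at 4 hits), a first-exon length factor (0.2), and proximity to
the 3' end (0.1), standing in for splicing–polyadenylation coupling. The
first-exon factor is `exp(−max(0, len − 374)/430)`: flat up to the ~374 nt
human average first-exon length, decayed to ~e⁻¹ by the ~800 nt mark that
counts as a large first exon, and severe beyond — a smooth monotone choice
consistent with the qualitative observations that motivated it (splicing
restored to 100 % when a 3-kb first exon was removed, intermediate when
halved). ESE hits are hexamers *starting* 5–10 bases from the junction on
either side, reported with signed offsets (−7 = starts seven bases into
the upstream exon); start-based counting is the reading consistent with a
(−7, +10) worked pair, and the hexamer may cross the junction because the
exons are contiguous before intron insertion. The packaged hexamer list is
a toy set; the genuine RESCUE-ESE list is user-suppliable as a plain text
file.

`predict_splice_products()` enumerates all donor–acceptor pairings plus
the unspliced product; a cryptic donor *d* nt upstream of the intended one
yields a product exactly *d* nt shorter, the diagnostic signature by which
mis-splicing between neighbouring insertion sites is recognised (the
package's worked example uses the 69-nt case). `find_branch_point()` is a
purely diagnostic YTNAY scan 15–45 nt upstream of the acceptor —
branch-point biology beyond the motif is out of scope.

## Resistance recoding

`recode()` replaces every codon overlapping the target window with the
synonymous alternative that maximises nucleotide differences, tie-broken by
the closest within-family usage fraction (packaged human table; a rare-codon
floor of 0.05 applies when avoidable). Met/Trp have no synonym and stop
codons are never altered; both warn. Protein invariance is checked on every
call. One deliberate limit: the maximise-differences rule is an involution
on two-codon families (GAA↔GAG and friends), so *re*-recoding an already
recoded region partially reverts it — recoding is a one-shot operation, and
the tested guarantee is that a single application never decreases the guide
mismatch count and that re-application never reconstructs the exact
original target region. `verify_resistance()` scores the best alignment of
the guide's target against the recoded region (defaults: ≥4 total and ≥2
seed mismatches to pass), and `audit_new_signals()` flags newly created
donor-like hexamers (≤2 mismatches from consensus), plausible new acceptor
contexts, and net ESE gain/loss.

## Small-RNA validation and the simulator

`trim_and_filter()` (suffix–prefix adaptor matching, minimum 5-nt overlap;
18–25 nt retention window — the window is configuration, since library
protocols also quote ~18–24) feeds `align_reads()` (exact or ≤1-mismatch
substring matching; leftmost hit wins and is flagged on multi-mapping;
arm assignment by read start, loop-starting reads excluded from arm
fractions) and `arm_profile()` (arm fractions, guide fraction, 5'-end
fidelity, per-arm length histograms, per-position incidence).

`simulate_reads()` is the matched generator: arm choice is a Bernoulli
draw, the 5' start jitters around the intended first base (intron position
1 for the 5' arm; the 3'-arm boundary otherwise), lengths come from
per-arm distributions, and substitutions occur at a per-base error rate.
Its defaults emulate the published behaviour of a well-processed 5'-arm
mirtron library — arm fraction 0.986, 5'-start fidelity 0.988, modal
lengths 22 (5' arm) and 20 (3' arm) — values reported from real libraries
whose raw reads are not publicly retrievable, which is precisely why the
simulator exists: the pipeline-closure property (simulate → trim → align →
profile recovers the simulation parameters within binomial sampling error
at n = 10,000) is the reproducible stand-in for those library statistics.
What passing that closure shows is internal consistency of simulator and
profiler; what it cannot show is fidelity to real Dicer/RISC biology —
real libraries carry 3'-end trimming, non-templated additions and
expression-dependent biases the simulator does not model.

## Numerical and degenerate-input choices

* Scanning an empty or too-short transcript returns an empty table, not an
  error; a transcript with no compatible windows flows through the full
  pipeline as a warning-bearing report.
* Zero aligned reads yield an explicit empty profile (`status = "empty"`),
  never a division error.
* Ranking ties break on (transcript, position, arm) so all orderings are
  stable and runs are byte-reproducible; the simulator requires a seed and
  identical seeds give identical FASTQ files.
* Splicing efficiency is undefined when both band signals are zero
  (error); fluorescence normalisation subtracts mock from the controls too,
  otherwise controls would not normalise to a mean of exactly 1.
* Test and acceptance problem sizes — 1000 random transcripts for the
  scanner oracle, all 4096 donor hexamers, 10,000 simulated reads, 100
  random CDS regions — were chosen as the smallest sizes at which the
  property suites are statistically meaningful (3 binomial standard errors
  at n = 10,000 separates 0.9 from 0.89) while running in well under a
  minute each.

## Known limitations

* ΔG is a layout score, not structure prediction; competing folds,
  bulges and coaxial stacking are not modelled.
* Off-target counting is occurrence-based; no expression weighting, no
  seed-pairing thermodynamics.
* Donor/acceptor scoring is consensus- (or user-PWM-) based, deliberately
  simpler than machine-learned splice-strength models; NetGene2-class
  predictions are out of scope and their role is filled by these
  transparent scores.
* The insertion-site composite reproduces the *ranking logic* of the
  observations that motivated it; its weights are heuristics, not fitted
  parameters.
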