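# mirtronkr

Design and validation toolkit for **artificial mirtrons** and
**knockdown-replacement (KR)** gene-therapy constructs, in R.

Mirtrons are introns that, once spliced out of their host transcript and
debranched, fold directly into pre-miRNA hairpins — so the splice sites, not
Drosha/DGCR8, define the RNAi effector. That makes them attractive for KR
therapy of dominant diseases (e.g. polyglutamine ataxias): a single construct
can express an RNAi-resistant replacement copy of a gene while silencing the
endogenous alleles from an intron nested inside it, mutation- and
SNP-independently. It also makes their design unusually constrained: the
guide strand must simultaneously be a good siRNA **and** a functional intron
terminus.

`mirtronkr` implements that whole design loop for computational biologists
and RNAi tool builders:

* **Target scanning** — enumerate transcript windows whose reverse
  complement (the guide) can serve as a 5' arm (guide starts `GT`, the
  donor) or 3' arm (guide ends `AG`, the acceptor); score donor consensus
  (`GTAAGT`), polypyrimidine-tract (PPT) purity in the 10 nt before the
  terminal `NAG`, and achievable 3'-end pairing bias for RISC loading;
  exhaustive k-mismatch and seed-complement off-target counts.
* **Hairpin engineering** — assemble `5' arm + loop + 3' arm` introns,
  edit the passenger strand (enforce splice termini, purge PPT purines,
  keep the guide's 3'-terminal block Watson–Crick paired), estimate ΔG with
  a nearest-neighbor model over the designed pairing, and derive controls:
  unspliceable (single donor G→A), shRNA (last two intron bases swapped for
  a U6 terminator), and destabilised variants (passenger-only substitutions
  that raise ΔG).
* **Insertion-site analysis** — rank exon–exon junctions of a transgene by
  exonic consensus (`CAAG|G`), ESE hexamer support 5–10 nt from the
  junction, first-exon length (penalised past the ~374 nt human average)
  and distance to the 3' end; enumerate intended/cryptic/unspliced splice
  products.
* **Resistance recoding** — silent codon replacement over the target window
  (maximum nucleotide change, usage-matched), resistance verification
  against the guide, and auditing for accidentally created splice signals.
* **Sequencing validation** — adaptor trimming, 18–25 nt filtering,
  hairpin alignment, and arm-profile statistics (arm fractions, 5'-end
  fidelity, length distributions, per-position incidence), with a seeded
  read simulator for calibration.
* **Assay arithmetic** — splicing efficiency (spliced / total),
  mock-and-control fluorescence normalisation, relative dual-luciferase
  ratios.

Everything is tidyverse-shaped: tabular results are tibbles, fitted objects
have `tidy()` / `glance()` methods, and `autoplot()` / `plot_*()` helpers
produce ggplots.

## Worked example

```r
library(mirtronkr)

# self-consistent synthetic inputs: transcript == transgene CDS, with a
# planted splice-compatible target and a CAAG|G insertion junction
man <- generate_fixtures(tempfile("fx"), seed = 3)
report <- run_kr_pipeline(man$file[1], man$file[2])
report
#> <kr_report> transcript synthetic_transcript -> transgene synthetic_transgene
#>   targets: 65 candidate site(s)
#>   hairpin: guide TCTTCACATCCTTGTTTGGAG (3p arm), dG -31.42 kcal/mol
#>   insertion sites: 38 junction(s)
#>   resistance: 9 total / 2 seed mismatches -> pass
```

The report says: 65 transcript windows satisfy a splice-arm rule; the
top-ranked guide is a 3'-arm design (it ends `AG`, the acceptor) whose
hairpin has an estimated ΔG of −31.4 kcal/mol; the transgene offers 38
candidate intron junctions; and after silent recoding the target window
differs from the guide at 9 positions (2 in the seed), meeting the
≥4 total / ≥2 seed resistance thresholds.

Individual steps compose with the pipe:

```r
sites <- read_fasta(man$file[1]) |> scan_targets() |> score_targets() |> rank_targets()
top5p <- dplyr::filter(sites, arm == "5p")          # best 5'-arm design
hp    <- build_hairpin(top5p$guide[1], arm = "5p")
glance(hp)          # one-row summary: termini, dG, pair classes
tidy(hp)            # per-position pairing table
make_unspliceable(hp)  # donor G>A control
to_shrna(hp)           # U6-terminated shRNA equivalent

reads <- simulate_reads(hp, sim_params(n_reads = 10000, seed = 1))
prof  <- reads |> trim_and_filter() |> align_reads(hp) |> arm_profile(hp)
prof
#> <arm_profile> 9813 aligned reads: 98.6% 5' arm / 1.4% 3' arm; guide (5p) 98.6%, 5'-end fidelity 99.2%
autoplot(prof)      # per-position incidence, coloured by arm
```

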