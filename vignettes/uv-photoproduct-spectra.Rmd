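---
title: "Attributing UV mutation spectra to photoproduct classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing UV mutation spectra to photoproduct classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvspectra)
library(dplyr)
```

## The experimental design this package analyses

UV light deposits several chemically distinct lesions in DNA. Cyclobutane
pyrimidine dimers (CPDs) form at the four dipyrimidines (TT, TC, CT, CC)
and are by far the most abundant; pyrimidine (6–4) pyrimidone
photoproducts (6–4PPs) favour TC and TT; and rarer "atypical"
photoproducts form at purine-containing dinucleotides, notably the
thymine–adenine photoproduct (TA-PP) at TA and a lesion at AC
dinucleotides that produces tandem AC>TT doublets. Photolyases are
light-driven repair enzymes, each specific for one lesion class, which
makes them a subtractive instrument: passaging a GG-NER-deficient diploid
yeast strain through repeated UVB exposures with or without a CPD
photolyase (and/or a 6–4PP photolyase), then sequencing clonal isolates,
turns "which lesion causes which mutation class?" into a set of
between-strain comparisons. This package implements the computational
side of that design:

1. **Variant filtering** (`read_variants()`, `filter_variants()`) —
   diploid calls with at least 10 reads and a 45% allele fraction (both
   inclusive), mitochondrial calls removed, and identical variants seen
   in more than two isolates of the same passaging replicate removed as
   pre-existing (`apply_recurrence_filter()`). Adjacent SNV pairs merge
   into doublet substitutions; runs of three or more are set aside
   (`call_doublets()`).
2. **Spectra** (`build_sbs_matrix()`, `build_dbs_matrix()`) — per-isolate
   counts over the 96 pyrimidine-centric trinucleotide SBS classes and
   the 78 canonical doublet classes, with per-class means, SEM (sample
   SD / sqrt(n)) and per-isolate totals.
3. **Attribution** (`fold_reduction_table()`, `classify_photoproduct()`,
   `attribute_mutation_counts()`) — per-class fold reductions between a
   no-photolyase control and a photolyase strain, tested with Welch's
   unequal-variance t-test; classes placed in the CPD / 6–4PP fold plane;
   and the subtractive count arithmetic (mean over replicates of
   per-replicate median totals, control minus treated).
4. **Strand asymmetry** (`assign_transcriptional_strand()`,
   `asymmetry_table()`) — transcription-coupled repair removes lesions on
   the transcribed strand (TS) of genes, so photoproduct-derived mutation
   classes are enriched on the non-transcribed strand (NTS). Counts are
   normalized by the strand-specific abundance of each class's context
   across gene bodies and tested with a 1-df chi-squared test under
   Bonferroni correction. Classes *significantly enriched on the TS*
   (normalized ratio < 1) indicate a lesion on the opposite strand:
   re-expressed on the complementary strand by
   `reverse_asymmetry_report()`, T>A in NTA becomes A>T in TAN — the
   TA-photoproduct signature.
5. **Lesion quantification** (`calibrate_ladder()`,
   `lesion_frequency()`) — alkaline-gel densitometry of
   lesion-specifically cleaved genomic DNA gives a fragment-size
   distribution; under Poisson lesion placement the lesion frequency
   follows from the mass-weighted median fragment size. Combining lesion
   totals with attributed mutation counts gives the *mutagenic
   potential* of each lesion class (`mutagenic_potential()`).

## Statistical and numerical choices

**Pyrimidine-centric collapse.** A substitution whose reference base is a
purine is re-expressed as its reverse complement, so each double-stranded
change has one canonical name. The collapse keeps a flag recording which
reported strand carried the pyrimidine; the strand-asymmetry module is
built on that flag. Doublets collapse onto ten canonical reference
dinucleotides; for the four self-reverse-complementary references
(AT, CG, GC, TA) the lexicographically smaller alternate breaks the tie,
which makes the 78-class catalogue exhaustively decidable (a property the
tests verify by brute force over all 144 changes).

**Context censuses.** Normalization abundances count literal occurrences
of each pyrimidine-central trinucleotide on the designated strand: both
strands of the whole genome for genome-wide normalization, or the coding
(NTS) strand of gene bodies and its complement for the asymmetry
analysis. Stretches covered by genes on both strands are excluded
(NTS/TS is undefined there), as are windows containing N. Census windows
are counted fully inside gene bodies, so a mutation at the outermost base
of a gene uses a context window that leaks one base past the boundary; at
gene lengths of hundreds of bp the discrepancy is negligible.

**Welch's test with degenerate groups.** Rare classes produce groups with
zero variance; `t.test()` refuses these, but they carry an obvious
reading: equal constants are indistinguishable (p = 1), unequal constants
are perfectly separated (p = 0, flagged `degenerate`). Everywhere else
the closed-form Welch statistic matches `t.test()` to 1e-10 (tested). No
multiple-testing correction is applied to fold tables; Bonferroni is
applied only to the asymmetry chi-squared family, with the divisor equal
to the number of classes meeting the min-count threshold in that call.

**Mann–Whitney concordance.** Replicate concordance of per-isolate totals
uses the exact U distribution for combined n up to 20 without ties, and
the normal approximation with tie and continuity correction otherwise —
matching `wilcox.test()` to 1e-10 (tested).

**Fold-plane classification.** The quadrant reading of the fold plane
(strong CPD-photolyase reduction only → CPD-derived; strong 6–4PP
reduction only → 6–4PP-derived; both → mixed; neither → atypical) is
qualitative in origin. The default threshold of 2.0-fold on both axes is
this package's operational choice, exposed as a parameter
(`cpd_threshold`, `pp64_threshold`), not a value asserted by the
underlying experiments.

**Poisson fragment correction.** With lesions placed as a Poisson process
at rate φ per kb, fragment lengths after complete cleavage are
exponential(φ), but a stained gel reports *mass*, which length-biases the
distribution to gamma(2, φ); its median is ≈ 1.6783/φ. The default
`correction = 1.678` therefore converts the median-intensity fragment
size into φ. Because the exact convention of the prior gel-quantification
method cannot be recovered from its description, `correction = 1` (naive
reciprocal) is available for comparability. The estimator is validated
end-to-end: simulated Poisson breakage at 1.26/kb on 50-kb strands with
0.05/kb background cutting is recovered within 10% (test and acceptance
script). The ladder ships as an editable table of HindIII-λ fragment
sizes (`lambda_hindiii_sizes()`), not a constant; calibration is linear
interpolation of log10(size) against migration with linear extrapolation
beyond the outermost bands. Background (no-enzyme) frequency is
subtracted; a negative net frequency floors at zero with a flag, since
background can exceed signal in noisy lanes.

**Filtering order.** The recurrence rule counts carrier isolates in the
record set it is given, so it does not commute with the per-site filters:
removing a low-fraction carrier first can change a variant's carrier
count from three to two. The pipeline fixes the order used in the
original analysis — site thresholds first (they were applied at calling),
then the recurrence screen on the compiled table — and the cascade is
idempotent.

## What the synthetic cohorts emulate

`simulation_config()` + `generate_genome()` + `simulate_cohort()` produce
a complete desk-scale study with known ground truth: a random nuclear
contig (yeast-like 38% GC) with non-overlapping genes on both strands and
a small excluded mitochondrial contig; lesion channels that deposit
Poisson lesions across their target-dinucleotide occurrences on both
strands over 15 passages; photolyase repair as per-strain, per-channel
thinning; transcription-coupled repair as a further thinning of
template-strand lesions inside genes (`ts_suppression`, default 4, a
moderate bias of the kind TC-NER produces); direct conversion of each
surviving lesion into an SBS or doublet via per-context outcome
distributions; Poisson read depth (mean 60) with binomial heterozygous
allele fractions; and injected recurrent "pre-existing" variants plus
mitochondrial variants so the filters have something to remove.

Default channel rates are presets sized to the qualitative proportions
the photolyase experiments established — the CPD channel carries roughly
60% of the burden, so the CPD-photolyase strain retains about 40% of the
control count, and the strain expressing both photolyases keeps only the
few-percent atypical remainder — with CPD outcomes C>T-heavy at TC/CC
plus non-canonical T>C/T>A/T>G at CT/TT, 6–4PP outcomes T>C at the 3' T
of TT and C>A at TC, TA-PP giving A>T at the A of TA, and the AC
photoproduct giving AC>TT doublets. They are presets, not fitted
parameters.

What the simulator deliberately does **not** model: replication and
translesion-synthesis biochemistry (lesions convert directly to mutations
with channel-specific probabilities folded into the rates), selection,
sequencing-read simulation, mappability artefacts, copy-number changes,
and clustered damage beyond independent per-lesion placement. Passing the
simulation-recovery tests therefore shows the *statistics* are computed
correctly at realistic scales, not that real cohorts are free of those
complications.

The default problem sizes — a 100 kb genome, 8–12 isolates per strain,
two replicates, ~300 mutations per control isolate, 4–5 thousand strands
per simulated gel lane — are chosen so every property is measured with
comfortable statistical resolution while a full test run stays
interactive. The genome-scale numbers (hundreds of mutations per isolate
over 12,070 kb) enter only through the attribution arithmetic, which is
scale-free.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_isolates = 8)
gg  <- generate_genome(cfg, seed = 1)
coh <- simulate_cohort(cfg, gg$genome, gg$genes, seed = 2)

res <- run_pipeline(run_config(
  genome = gg$genome, genes = gg$genes, variants = coh$variants,
  comparisons = list(list(control = "No PL", treated = "CPD PL"),
                     list(control = "No PL", treated = "6-4PP PL")),
  min_total_fold = 20, min_total_asymmetry = 20))

pipeline_report(res)
autoplot(res$sbs)                      # per-class mean spectra
plot_asymmetry(res$asymmetry)          # NTS/TS ratio vs class count
plot_fold_plane(res$calls)             # CPD vs 6-4PP fold plane
```

## Known limitations

* Strand assignment and the gene censuses ignore expression level; all
  annotated genes count equally, and there is no TC-NER kinetic model.
* The asymmetry analysis discards intergenic mutations entirely.
* The fold-plane labels depend on the 2.0-fold default thresholds;
  classes near a threshold should be read from the fold table, not the
  label.
* Whether genome-wide trinucleotide normalization should be computed over
  the whole genome or gene bodies only is not settled by the source
  analysis; both are available (`strand_mode` in `context_census()`), and
  the asymmetry table uses gene bodies, which is the consistent choice
  for an NTS/TS comparison.
* `lesion_frequency()` assumes complete enzymatic cleavage at lesions and
  random lesion placement; partial digestion biases the estimate
  downward.
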