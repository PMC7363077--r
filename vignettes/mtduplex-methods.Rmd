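---
title: "Models and methods behind mtduplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtduplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtduplex)
```

# The problem

De novo mitochondrial mutations arise at frequencies of roughly
10^-7^–10^-6^ per base pair — several orders of magnitude below the error
rate of standard short-read sequencing.  Duplex sequencing closes that gap
by tagging both strands of each DNA template with random barcodes before
amplification: reads sharing a tag family are collapsed into a single-strand
consensus sequence (SSCS), and the two strand consensuses of one duplex are
compared to form a duplex consensus sequence (DCS).  A base is trusted only
when both strands agree, which suppresses PCR errors and single-strand
damage artifacts to below the frequency of true low-level variants.

`mtduplex` implements the full computational chain for a two-generation
mouse pedigree design: consensus calling from barcoded reads, circular-
genome pileup and variant calling, classification of variants into
tissue-specific de novo mutations, early somatic mutations and inherited
heteroplasmies, mutation-frequency statistics, an hN/hS selection test, a
germline bottleneck estimator, and a binomial mixed-effects model of
mutation frequency.  A seeded simulator generates pedigrees, bottleneck
transmission and duplex read families so that every stage is testable
without external data.

# Reference genome model

The reference is a circular sequence with a functional feature table
(D-loop, protein-coding, tRNA, rRNA, other noncoding).  Coordinates are
1-based inclusive and wrap silently at the origin, so pileup over the
circular genome needs no relinearisation; a two-window merge
(`merge_edge_windows()`) exists for parity with externally mapped data that
were aligned to a relinearised reference.  Overlapping annotations are
resolved by the fixed precedence D-loop > protein-coding > tRNA > rRNA >
noncoding, which makes the compartment labelling an exact partition (the
compartment sizes always sum to the genome length).  Codon logic uses the
vertebrate mitochondrial genetic code (translation table 2), forced by the
organism.

The packaged reference (`synthetic_mt_genome()`) is *synthetic*: a
deterministic 16,299-bp sequence whose layout mirrors the mouse mtDNA gene
order and whose compartment totals match the study annotation exactly
(D-loop 877 bp, protein-coding 11,331 bp, tRNA 1,499 bp after the pedigree
insertion, rRNA 2,536 bp, other noncoding 57 bp).  Applying the pedigree
edits — an A inserted after position 9,821 inside TrnR and a T>C change at
9,461 in ND3 — yields the 16,300-bp working genome.  Coding regions are
generated codon-wise with a start codon, terminal stop and no internal
stops, so selection analyses are well defined.  It is not the RefSeq
sequence; real annotations can be supplied as a feature TSV or parsed from
a GenBank flat file.

# Consensus calling

Parameters follow the established duplex practice:

* **Barcode correction** — 12-nt tags per mate (24-nt combined key), merged
  greedily into higher-count tags within a Hamming distance of 3; ties are
  broken lexicographically so correction is deterministic.  Correction here
  is purely tag-sequence based; no mapping step is involved.
* **SSCS** — minimum family size 3; a consensus base requires at least 70%
  of the member reads (the comparison is `>=`, "at least 70%"), otherwise
  `N`.  Base qualities are carried but not used in voting; the quality
  filter applies later at pileup.
* **DCS** — formed only when both strand SSCSs exist; a base is emitted only
  where the strands agree and neither is `N`.  The two strands of a duplex
  carry swapped tag pairs, and the duplex is keyed by the lexicographically
  smaller arrangement, with mate comparison crosswise (mate 1 of one strand
  against mate 2 of the other).
* **Trimming** — the first 12 nt of every consensus mate are removed:
  end-repair during library preparation can write the same error into both
  strands near fragment ends, which duplex consensus cannot remove.

Families with unequal member read lengths are rejected rather than padded —
the simplest behaviour consistent with fixed-length sequencing.

# Variant calling

Aligned consensus mates are filtered (mapping quality strictly greater than
20, paired and properly paired; the variant-calling step itself uses the
separate >=50 convention of naive callers, both exposed as config keys),
overlapping mate intervals are clipped so one template contributes one
observation per position, and per-site base counts are accumulated at DCS
and SSCS level with `N` and sub-quality-20 bases excluded.  Every
non-reference base with at least one supporting DCS becomes a call:
single-molecule variants are the main object of study.  Allele frequencies
are reported from DCSs, except that when the DCS minor-allele depth is
below 5 the SSCS frequency is substituted — SSCS molecule counts are about
3-fold higher, so low-frequency MAFs are better measured there.  Indels are
out of scope (substitution-only), which also makes indel left-alignment a
no-op.

# Classification and filtering

Variants are classified by presence patterns across tissues and the
pedigree:

* **inherited** — present in both somatic and germline tissues of one
  individual, or in two generations of a pedigree;
* **early somatic** — present in both somatic tissues of an individual
  whose germline was assayed and clean (individuals without germline
  samples cannot yield this class);
* everything else is a **putative tissue-specific de novo** candidate.

Candidates are then filtered: a (site, alt) seen in more than three samples
dataset-wide (both pedigrees jointly) is a hot spot or a low-frequency
segregating variant and is excluded; occurrences in up to three samples are
retained because chance recurrence is expected at these mutation
frequencies.  Recurrence is keyed on (site, alt), not site alone, because
different alternate alleles are independent events.  Events supported by
more than one molecule in a sample count as a single mutation event (one
mutational origin), with the support retained for reporting.  A>T/T>A
candidates in enzymatically fragmented samples are excluded as
fragmentation artifacts — the artifact is written into both strands during
end preparation, so it survives duplex consensus; this deliberately
sacrifices some true A:T transversions in those samples.  A user-supplied
site exclusion list stands in for BLAST-based Numt screening.

# Frequency statistics

The mutation frequency of a stratum is the summed mutation count divided by
the summed sequenced nucleotides (region length x mean DCS depth, summed
over samples) — denominators are summed, never frequencies averaged.
Type-specific frequencies divide by the sequenced bases able to produce the
type (e.g. C>T by the sequenced C count).  Counts get exact (Garwood)
Poisson intervals; group comparisons on aggregated counts use Fisher's
exact test (two-sided); per-animal median comparisons use one-sided
permutation tests on the median difference.  The permutation p-value uses
the add-one Monte-Carlo estimator, which is conservative and never zero;
when the number of label arrangements is at most `n_perm` the test switches
to exhaustive enumeration and returns the exact tail fraction.  The default
`n_perm` is 10^4^ in the pipeline report (configurable upward; tests use
exhaustive or small Monte-Carlo runs).  Multiple testing is controlled with
Benjamini–Yekutieli FDR by default (valid under dependence), with plain
Benjamini–Hochberg selectable.  Spectra are reported as 12 directed types
on the reference (light) strand plus the 6-type pyrimidine-collapsed form;
a C (or paired G) in a 5'-CG-3' dinucleotide on either strand defines a CpG
site, and the CpG split is applied to C>T/G>A transitions only.  Two
spectra are compared with Pearson's chi-squared using Monte-Carlo p-values,
since expected counts are routinely small.

# Selection: hN/hS

Synonymous and nonsynonymous site counts follow Nei–Gojobori: each codon
position contributes the fraction of its three substitutions that preserve
the amino acid, so every codon contributes exactly 3 sites.  hN is the
nonsynonymous count per nonsynonymous site and hS the synonymous count per
synonymous site; stop and start changes count as nonsynonymous.  The
neutrality test bootstraps the null: each of the (default 100) replicates
places the observed number of mutations on coding sites, drawing types from
the observed 12-type spectrum and sites uniformly among coding positions
offering that type, and the two-sided empirical p-value compares the
observed ratio with the replicates (add-one correction).

An important subtlety: unweighted Nei–Gojobori sites assume all
substitutions are equally likely, so the neutral expectation of hN/hS is 1
only under uniform placement.  Under a transition-biased spectrum the
neutral ratio falls below 1 (transitions are disproportionately
synonymous) — which is precisely why the null is generated from the
observed spectrum rather than compared with the constant 1.  Whether the
null should preserve the transition/transversion split per compartment is
not determinable from the available description; genome-wide coding-region
weighting is the implemented default.

# Heteroplasmy drift and the germline bottleneck

Inherited heteroplasmies are analysed on minor allele frequencies with the
DCS/SSCS source rule above.  Sites are labelled by pedigree sharing
(pup-only, mother-and-pups, several-mothers), allele frequencies are
correlated between tissues (squared Pearson correlation of untransformed
MAFs), and drift is quantified by the variance of MAFs normalized by
p(1-p), whose expectation under binomial drift through N segregating units
is 1/N.

The effective bottleneck is estimated per (individual, site) as
N~ij~ = p~ij~(1-p~ij~)/sigma^2^~ij~, where p~ij~ is the parent reference
frequency (mean across brain and muscle) and sigma^2^~ij~ is the mean
squared deviation of the n~ij~ offspring (oocyte or pup) frequencies from
p~ij~ — deviations from the parent value, divided by n, exactly as the
estimator defines them.  The point estimate is the arithmetic mean of the
N~ij~ and the confidence interval resamples the N~ij~ with replacement
(1,000 draws).  Entries with p~ij~ outside (0,1) or zero variance are
excluded and counted rather than producing infinite values.

At study-scale mutation loads the presence-based inherited rule is also
satisfied by chance co-occurrence of unrelated single-molecule de novo
calls at one site.  Such sites carry near-zero parent frequencies and
all-zero offspring, so each contributes an N~ij~ near 1/p and would
dominate the bottleneck mean.  The pipeline report therefore admits a site
into the drift analyses only when its largest per-sample MAF reaches 0.2%
(just below the smallest real segregating frequencies the design emulates)
and at least three samples carry it; both thresholds are `run_all()`
arguments and the classifier itself is unaffected.

Users should know that this estimator is strongly right-biased at small
offspring counts: sigma^2^ estimated from n offspring has the dispersion of
a chi-squared with ~n degrees of freedom, so E[1/sigma^2^] exceeds
1/E[sigma^2^] by a factor near n/(n-2) under normality (about 1.5 at
n = 6), and individual N~ij~ values are heavy-tailed.  With few sites the
bootstrap interval is accordingly enormous; with many sites it concentrates
around the biased mean.  The package reports the estimator as defined and
leaves the bias to the interpretation, as the original formulation does.

# The mixed-effects frequency model

Observations are cells: one per individual x tissue x compartment (D-loop
vs outside) x mutation-type class (transversions, A>G/T>C, C>T/G>A), with
the mutation count and the number of sequenced nucleotides able to produce
the class (depth x compartment content of the class's reference bases).
Single oocytes are combined per individual; cells under 200,000 sequenced
nucleotides are dropped to avoid low-depth bias.  The model is binomial
with logit link — the count out of the nucleotide total, equivalent to a
frequency response weighted by the total — with treatment-coded fixed
effects (baselines: mother, brain, D-loop, transversion) and a random
intercept per individual, fitted by Laplace approximation (`lme4::glmer`,
bobyqa optimizer).  Coefficients get Wald tests; each variable gets a
likelihood-ratio test against the reduced refit; the random effect is
tested against the fixed-only GLM with the naive chi-squared reference
(conservative at the boundary).  Pseudo-R^2^ uses the latent-scale
decomposition with the logit distribution-specific variance fixed at
pi^2^/3: marginal = fixed-effect linear-predictor variance over the total,
conditional adds the random-intercept variance to the numerator, and the
partial pseudo-R^2^ of a variable is
((1-R^2^~red~)-(1-R^2^~full~))/(1-R^2^~red~) from the marginal values of
the full and reduced fits.  A second model adds two-way interactions
between mutation type and each other variable, tested as a block by LRT.

# The simulator

`sim_config()` defaults encode the study conditions: two pedigrees with
8 mothers (~10 months) and 28 pups (~20 days); brain and muscle for every
animal, single oocytes and an oocyte pool for females; median DCS depths of
2,050x (brain), 1,986x (muscle), 133x (single oocytes) and 932x (pools)
with lognormal per-sample scatter; per-tissue mutation rates equal to the
reported median frequencies (e.g. brain 1.2x10^-6^/bp in mothers vs
4.7x10^-7^/bp in pups); a 3-fold D-loop rate multiplier; a
transition-biased 12-type spectrum with the G>A/C>T and T>C/A>G strand
asymmetries; ~7% of de novo events supported by more than one molecule; 28
inherited heteroplasmies with log-uniform founder MAFs between 0.3% and
30%, split across the three sharing origins in the observed 17:7:4
proportions; a germline bottleneck of 85 segregating units (matching the
magnitude estimated from pup data); and duplex families with 12-nt tags, a
5-nt spacer and mean size 8 per strand (the 6–12 range).  Female pups
contribute 1–4 single oocytes each (a deterministic cycle approximating the
reported 1–8 spread); mothers contribute 6.  Values the study
does not state — the somatic replication pool (5,000 units, giving the
near-perfect somatic MAF correlations), the early somatic rate (1.5 events
per animal, matching 54 events over 36 animals), the artifact rate, the
fragment length distribution, and a lognormal per-individual mutation-rate
multiplier (log-scale SD 0.15, unit mean, emulating the minor but
detectable between-animal heterogeneity that motivates the model's random
intercept) — were chosen once as field-realistic and are documented here.  Oocyte turnover in mothers is exposed as extra binomial
rounds (`mother_turnover_rounds`), defaulting to off because the process is
not quantified.

Drift is a single binomial draw per transmission, which is exactly the
variance structure the bottleneck estimator assumes.  Randomness is one
documented stream seeded from `seed`; read emission derives a per-sample
substream as `(seed + 104729 * sample_index) mod (2^31 - 1)` so single
samples can be re-emitted reproducibly.

Two output levels exist.  `simulate_variant_calls()` produces
consensus-level per-sample variant tables directly (planted events at their
molecule counts, heteroplasmies binomially sampled at each sample's DCS and
SSCS depths) — this is the study-scale path used by `run_all()`, since
frequency estimates depend only on counts and depths.
`emit_read_families()` emits actual barcoded read pairs with per-base
errors, family-size scatter and template-level A>T/T>A artifacts for
enzymatic samples, plus a sidecar of true template origins that stands in
for an aligner; `run_read_pipeline()` pushes one sample through tag
correction, consensus, trimming, placement, clipping, pileup and calling.
The simulator does not emulate base-quality realism beyond a flat error
rate, Numt reads, indels or chimeras; passing tests therefore demonstrate
the correctness of the computational chain under the stated model, not
robustness to every artifact class of real libraries.

# Problem sizes and runtime choices

The test suite and the acceptance script run the full consensus-level
pipeline at study scale (188 samples, 16,300-bp genome, ~2,500 calls), the
read-level path on single samples at reduced depth (8x) and read length
(120 nt), permutation calibration on 1,000 exchangeable datasets at 300
permutations each, bottleneck recovery on 200 sites x 6 offspring with
1,000-resample bootstraps, hN/hS calibration on a few hundred simulated
datasets of 150–600 mutations, and 100 mixed-model refits for coefficient
coverage.  These sizes keep a full run in a few minutes on one CPU while
leaving Monte-Carlo standard errors well inside the asserted tolerances.

# Known limitations

* The bottleneck point estimate inherits the small-n~ij~ upward bias
  discussed above; results should be read with the bootstrap interval.
* The recurrence filter and the two-generation inheritance rule both act on
  presence patterns, so at study-scale mutation loads a small number of
  chance co-occurrences is classified inherited; the same behaviour is
  inherent to the rule set itself.
* The hN/hS neutral reference is spectrum-dependent; comparing the raw
  ratio with 1 is only valid under uniform mutation.
* SAM input supports ungapped alignments only, consistent with the
  substitution-only scope.
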