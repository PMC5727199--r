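---
title: "Methods: calling barcoded Kras tumors from bulk amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling barcoded Kras tumors from bulk amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubahdr)
```

# The assay and its data

`tubahdr` analyzes multiplexed tumor-barcode sequencing of mice in which
somatic homology-directed repair (HDR) installs one of 13 Kras alleles —
wild type or one of the 12 non-synonymous single-nucleotide variants of
codons 12 and 13 — together with a clone-identifying random barcode at the
endogenous locus. Deep sequencing of a short amplicon spanning the variant
codons and the barcode region of bulk tumor-bearing tissue then reports, for
every clonal lesion in the organ, its allele, its barcode and a read count
proportional to its number of neoplastic cells. A normalization control
("spike-in": DNA from 5 × 10^5 cells of a clonal G12V line with a known
barcode) added before DNA extraction converts read counts into absolute cell
numbers.

## The barcode design is fixed by the genetic code

The 22-nt barcode region runs from the third base of Kras codon 14 to the
third base of codon 21. Its eight randomized ("wobble") positions are the
third-codon positions of residues Val14–Ile21, so randomization never
changes the protein. The allowed alphabet at each wobble position is
therefore the synonymous-codon set of its residue:

| residue | codon family | alphabet | size |
|---|---|---|---|
| Val14, Gly15, Ser17, Ala18, Leu19, Thr20 | NNN-fourfold | A/C/G/T | 4 |
| Lys16 | AAR | A/G | 2 |
| Ile21 | ATH | A/C/T | 3 |

which gives a barcode space of 4^6 × 2 × 3 = 24,576 and an independent
per-position frequency model with Σ(|alphabet| − 1) = 21 free parameters.
Three fixed "anchor" bases inside the region (positions 8, 9 and 14,
recoding Ser17 AGT→TCN and Leu19 TTG→CTN, both synonymous) differ from the
wild-type locus in every engineered allele, so HDR alleles are
PCR-distinguishable and unambiguous to parse. We derived the alphabets from
the codon structure rather than treating the two restricted positions as
free configuration: it is the only assignment simultaneously consistent with
the 24,576-barcode space, the 21-parameter frequency model, a
protein-neutral barcode, and the documented spike-in sequence (whose wobble
bases read `CGGGGTGC`). Alternative alphabets remain configurable through
`kras_design(wobble_alphabets = ...)`.

The 60-nt amplicon core is laid out as

```
prefix(9) | flank(7) | codon12 | codon13 | GT | barcode region(22) | flank(7) | suffix(7)
```

where `GT` is the invariant first two bases of codon 14. `parse_reads()`
validates every invariant base, decodes the codon pair against the 13 allele
classes, and checks each wobble base against its alphabet, returning reason
codes (`bad_length`, `anchor_mismatch`, `unknown_codon`,
`bad_barcode_base`) instead of errors.

# From reads to tumor calls

## Clustering sequence and error-rate estimation

Reads are merged (fixed-offset overlap merger, higher quality wins at
mismatches, pairs below 90% overlap identity rejected) and trimmed to the
*clustering sequence*: the 7-nt invariant flank upstream of codon 12 through
the 7-nt invariant flank downstream of the final barcode base. With the
2-nt codon-14 spacer this is a contiguous 44-mer (7 + 6 + 2 + 22 + 7). The
14 flank positions are invariant by design, so every mismatch observed there
is a sequencing or PCR error; the residual per-base error rate is their
read-weighted mismatch fraction (`estimate_error_rate()`). Reads with any
base below Q20 inside the window are rejected (the quality threshold is our
choice; the source data were quality-filtered upstream).

## Abundance p-value denoising

`denoise_pileup()` clusters unique clustering sequences greedily, in the
spirit of amplicon denoisers. For a sequence at Hamming distance *d* from
its cluster center, recurrent errors are expected to contribute
λ = reads(cluster) × (ε/3)^d reads, with ε the per-base error rate and
substitutions uniform over the three alternatives. The abundance p-value is
the Poisson tail P(X ≥ observed | X ≥ 1); while any sequence falls below the
threshold ω_A = 0.01, the most significant one founds a new cluster and all
sequences are reassigned to the center most likely to have generated them.
Our implementation deliberately simplifies the full denoising machinery: the
error model is a single uniform rate fixed in advance from the invariant
flanks, with no quality-score dependence and no self-consistency loop —
fixing ε externally removes the need for the estimation loop. With ε = 0 the
error model cannot generate mismatches, so every distinct sequence founds
its own cluster; this makes error-free simulations exactly recoverable,
including one-read lesions.

Cluster centers within Hamming distance 1 of a cluster ≥10^4-fold larger are
then removed as "shadows" — recurrent-error artifacts of very large lesions
(`remove_shadows()`). Their reads are discarded, not reassigned, and the
removed fraction is reported per sample. Under the uniform error model of
the simulator most shadow-like pileups are already absorbed by the abundance
p-value, so simulated shadow fractions are near zero; the filter matters for
real data where errors are position- and context-recurrent.

## Spike-in normalization and cutoffs

Each call's cell number is reads ÷ spike-in reads × 5 × 10^5. Lung analyses
keep tumors strictly above 100,000 cells — one fifth of the spike-in — where
replicate concordance is high; pancreas samples carry no spike-in, so an
internal cutoff of twice the largest wild-type call's reads per sample is
used instead, and sizes remain relative within a sample. Individually
dissected tumors can be flagged via `run_pipeline(dissected = ...)`: they
stay in tumor-number analyses but are excluded from size analyses, since
their residual bulk signal understates their true size.

# The barcode-collision model

Two independent tumors can draw the same barcode. With N tumors drawing
barcodes multinomially with probabilities p_i, the expected number of
collisions on barcode *i* is

C_i(p_i, N) = N p_i + (1 − p_i)^N − 1,

and the observed number of distinct barcodes satisfies
N_obs = N − Σ_i C_i(p_i, N) ≡ B − Σ_i (1 − p_i)^N. `solve_total_tumors()`
inverts this with Brent's method (bracket [N_obs, 100·N_obs], doubled until
the sign changes; absolute tolerance 10^−6), and `correct_collisions()`
divides each lesion's size by 1 + C_i so collisions do not inflate size
distributions in expectation. Two modeling choices were genuinely open:

* **The sum runs over all retained barcodes**, not only observed ones: this
  is the algebraically consistent reading (the right-hand side is the
  expected distinct count) and makes the fixed point well defined.
* **The solve is applied per sample and per variant.** The variant-barcode
  pair is the clone identifier, so tumors of different variants cannot
  collide, and barcode draws are independent across mice. N_obs is the
  group's number of distinct called barcodes.

The p_i come from the 21-parameter independent per-position frequency model
fitted to plasmid-library sequencing (`fit_barcode_frequencies()`). Residual
over-representation is handled by discarding the 10% of observed library
barcodes with the largest observed/modeled ratio (ties broken
lexicographically for determinism, count = floor(fraction × n_observed)) and
renormalizing (`exclude_frequent_barcodes()`); excluded barcodes are dropped
from downstream lung analyses. Barcodes containing a never-observed
nucleotide get p_i = 0 and are excluded before solving. Expected collision
fractions are reported, not asserted against any particular value — they are
strongly data-dependent, growing with the per-variant lesion count per
mouse.

# Per-variant statistics

Variant representation in the library is each variant's read fraction after
removing barcodes above the 98th percentile of pool-wide per-barcode
abundance (we chose pool-wide rather than per-variant trimming; the trim
exists only to keep jackpot pairs from distorting marginals, and pool-wide
is the simpler estimator with the same effect). The normalized tumor number
is count ÷ representation, scaled so WT = 1.

Enrichment tests against the WT and G12D references are two-sided Fisher's
exact tests on [[count_v, count_ref], [library reads_v, library reads_ref]]
— raw library reads preserve exactness and use all information — with
Bonferroni correction by the 12 mutant variants. When no WT tumor exists the
table has a structural zero; we use the exact binomial tail
p₁ = (1 − p_ref)^{count_v} with p_ref = rep_ref/(rep_ref + rep_v), doubled
for two-sidedness. This is a declared stand-in construction for a
generalized exact test, not a reproduction of any published variant of it.
Confidence intervals are percentile bootstrap (default 2000 resamples) over
the pooled tumor list of a genotype; a per-mouse block bootstrap would
capture mouse-level clustering but the pooled design matches how the
summaries are built. Spectra across genotypes are compared with the
"many cells" Pearson χ² (no continuity correction); expected cells below 1
trigger a warning but not a refusal.

# The synthetic-data generator

`simulate_plasmid_pool()`, `simulate_cohort()`, `simulate_sample_reads()`
and `simulate_multiregion()` generate data with the statistical structure
the analysis assumes, plus ground truth. Fixed study conditions:

* **Pool**: WT allele weighted 4× each mutant; independent per-position
  nucleotide skew (default weights 0.32/0.27/0.23/0.18 truncated to each
  alphabet — a mild synthesis-type imbalance).
* **Tumor sizes**: lognormal, median 2 × 10^5 cells and σ of log10 size
  0.5, truncated below at 10^3 cells. No size law is dictated by the assay;
  a heavy-tailed lognormal is the standard choice consistent with read
  counts spanning several orders of magnitude.
* **Oncogenicity**: tumors draw variants ∝ representation × multiplier;
  `default_multipliers()` spans 0.05 (WT — wild-type alleles essentially
  never seed tumors) to 10 (G12D), with codon 13 weaker than codon 12.
* **Reads**: pre-merged 60-nt cores, per-lesion counts multinomial around
  cells × reads-per-cell, constant Q37 qualities, iid per-base substitution
  errors at 10^−4 (about 1 error per 10^4 bases). `count_model = "exact"`
  emits deterministic counts for calibration tests.

The generator does **not** emulate PCR jackpotting, amplicon-length bias,
context-dependent or quality-dependent error rates, chimeras, or
Kras-locus copy-number gains. Passing tests therefore validate the
statistical machinery under the stated model, not robustness to those
real-data artifacts; the shadow filter and the spike-in caveats exist
precisely because real data deviate in those directions.

Cohort sizes in the test-suite and acceptance script (15 mice × ~150
tumors, 4 × 10^5 library reads, ~5 × 10^5 sample reads) were chosen as the
smallest sizes at which the recovery checks are statistically sharp; all
generators are bit-reproducible under a fixed seed.

# Clonal mapping and signature normalization

`match_clones()` groups calls across multi-region and metastasis samples by
exact (variant, barcode) equality — denoising has already collapsed
sequencing errors, so fuzzy matching would only re-admit artifacts. Groups
spanning ≥2 primary samples are region-continuity; groups containing a
metastasis link it to every primary member as a source candidate (ambiguity
is preserved, not resolved). Each edge carries a collision hazard
1 − (1 − p_i)^{n_partner}: the probability the pair recurs in the partner
sample by independent initiation. Within-sample sizes are scaled to the
largest tumor; plotted dot diameter is √(relative size).

`relative_induction()` sums tumor-extrinsic trinucleotide-signature
probabilities (pyrimidine-centric 96-class convention) over the 12 codon
12/13 mutations of a supplied CDS context and normalizes within them;
`normalize_prevalence()` divides observed human mutation counts by these
induction frequencies. The packaged signature and codon-usage tables are
synthetic fixtures (labeled as such) in the standard file formats; analyses
of real spectra should load the published tables. A mutation whose context
probability is zero in every included signature is an error by design — we
refuse rather than impute.

# Known limitations

* The collision correction is an expectation-level correction: it cannot
  identify which specific calls were collisions.
* The denoiser's uniform error model understates recurrent, context-specific
  errors; the shadow filter is the backstop for that regime.
* Absolute cell numbers inherit any PCR bias between the spike-in's locus
  and tumor alleles with intron indels; such bias is not modeled.
* Pancreas-mode sizes are relative within a sample only.
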