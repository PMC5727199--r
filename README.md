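# tubahdr

Quantitative analysis of multiplexed tumor-barcode sequencing for pools of
Kras variants engineered into somatic cells by homology-directed repair
(HDR).

In this assay, a viral library delivers HDR templates that install one of 13
Kras alleles — wild type or any of the 12 non-synonymous single-nucleotide
variants of codons 12/13 (G12A/C/D/R/S/V, G13A/C/D/R/S/V) — together with a
random 8-nucleotide barcode embedded in the synonymous third-codon positions
of residues 14–21 (a 24,576-barcode space). Every clonal tumor in a bulk
organ is then visible in amplicon sequencing as a unique variant–barcode
pair whose read count is proportional to its neoplastic cell number.
`tubahdr` turns those reads into called tumors with absolute sizes and
per-variant oncogenicity statistics.

## What the package computes

Starting from merged amplicon reads (FASTQ or tibble) and plasmid-library
sequencing of the vector pool:

1. **Read processing** — trim to the 44-nt clustering sequence; estimate the
   residual per-base error rate ε from the 14 invariant flank bases.
2. **Tumor calling** — abundance p-value denoising: a sequence at Hamming
   distance *d* from a cluster of *r* reads is expected to receive
   λ = r(ε/3)^d error reads; pileups with Poisson tail probability
   P(X ≥ count | X ≥ 1) < ω_A = 0.01 found new clusters. Shadow calls
   (1 mismatch from a ≥10⁴-fold larger lesion) are removed.
3. **Absolute sizes** — cells = reads ÷ spike-in reads × 5×10⁵, using the
   normalization control added to each sample; lung analyses keep tumors
   with > 100,000 cells.
4. **Collision correction** — barcode draws are multinomial with
   probabilities p_i from a 21-parameter per-position frequency model of the
   library; the expected collisions C_i(p_i, N) = N·p_i + (1−p_i)^N − 1 and
   the true tumor number N (solved by Brent's method from
   N_obs = N − Σ_i C_i) divide each lesion's size by 1 + C_i.
5. **Oncogenicity statistics** — tumor counts normalized by library
   representation and scaled to WT = 1; two-sided Fisher's exact tests
   against WT and G12D (Bonferroni-corrected), an exact structural-zero
   test when no WT tumors exist, and bootstrap 95% confidence intervals.
6. **Clonal mapping** — shared variant–barcode pairs link multi-region
   samples and metastases to their source tumors, with a model-based
   collision hazard per link.
7. **Signature normalization** — trinucleotide mutational-signature
   probabilities (96-class convention) give relative induction frequencies
   of the 12 mutations, used to normalize observed mutation spectra.

A seeded synthetic-data generator (`simulate_plasmid_pool()`,
`simulate_cohort()`, `simulate_sample_reads()`, `simulate_multiregion()`)
produces pools, cohorts and reads with ground truth for parameter-recovery
testing.

## Worked example

Simulate a 3-mouse cohort from a library pool and run the full pipeline:

```r
library(tubahdr)

pool  <- simulate_plasmid_pool(depth = 1e5, seed = 42)
truth <- simulate_cohort(pool, n_mice = 3, mean_tumors = 120, seed = 43)
reads <- simulate_sample_reads(truth, seed = 44)
run   <- run_pipeline(reads, pool, n_boot = 500, seed = 45)

run
#> <tubaseq_run> 3 sample(s), 321 calls (231 above cutoff)
#>   mean error rate: 0.000109; mean shadow fraction: 0

tidy(run)[, c("variant", "n", "relative", "ci_lo", "ci_hi", "p_vs_wt")]
#> # A tibble: 13 × 6
#>    variant     n relative ci_lo ci_hi   p_vs_wt
#>    <chr>   <int>    <dbl> <dbl> <dbl>     <dbl>
#>  1 G12A       14     56.2 14.7   304.  2.35e- 8
#>  2 G12C       26    104   28     542.  1.84e-16
#>  3 G12D       56    224.  63.2  1051.  5.10e-37
#>  4 G12R       33    138.  35.2   692.  9.64e-22
#>  5 G12S        6     23.6  3.94  150.  4.79e- 3
#>  6 G12V       54    214.  54.5  1011.  1.70e-35
#>  ...
#> 13 WT          1      1    0       1  NA
```

Reading the output: the estimated per-base error rate (1.09 per 10⁴ bases
here) comes from the invariant flanks of this run's reads; `n` is the number
of called tumors above 100,000 cells per variant; `relative` is the tumor
number normalized by each variant's library representation and scaled so
wild type equals 1 — G12D alleles seeded roughly 220× more tumors per unit
of representation than wild type in this simulation, mirroring the strong
codon-12 > codon-13 oncogenicity gradient the generator encodes. `p_vs_wt`
is the Bonferroni-corrected two-sided Fisher p-value against wild type.
`autoplot(run$summary)` draws the summary; `glance(run)` returns run-level
diagnostics (error rate, shadow fraction, expected collision fraction).

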