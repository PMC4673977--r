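# bsvar

SNP calling and genotype-corrected methylation from bisulfite sequencing
(WGBS/RRBS), in R.

Bisulfite treatment converts unmethylated cytosines to uracil, sequenced as
T. On the strand carrying the cytosine, a genuine C→T SNP and an unmethylated
C therefore look identical — and since most human SNPs fall in CpG context,
mistaking one for the other corrupts both the variant set and the methylation
levels computed from it. The two original strands convert independently,
though: Crick-strand reads at a reference C still read the unconverted base
and distinguish a true variant from chemistry. `bsvar` implements a caller
built on that observation, for anyone who needs genotypes and per-cytosine
methylation out of the same bisulfite alignments: methylome studies that must
remove SNP artefacts, and allele-specific methylation work that needs the
variants themselves.

## The method

1. **Strand-separated dynamic-matrix pileup.** One chromosome at a time, a
   matrix of per-position vectors records read counts and summed Phred
   qualities for all four bases on Watson and Crick strands separately
   (reference orientation; strand of origin from `ZS`/`XG` tags or FLAG).
   The matrix is allocated, filled, genotyped and released per chromosome.
   Reads are admitted at MAPQ ≥ 20 with a bisulfite-adjusted mismatch rate
   ≤ 0.02 (Watson C→T and Crick G→A differences excused); bases below Q15
   are not counted.

2. **Candidate screen.** Watson-T and Crick-A observations are
   conversion-ambiguous and excluded from *effective counts*; a site is a
   candidate when some non-reference allele reaches effective frequency
   ≥ 0.1 with ≥ 2 effective reads, at retained depth in [10, 1000].

3. **Approximate Bayesian genotyping.** Over the ten diploid genotypes,
   P(G|D) ∝ P(G) · ∏ᵢ P(Dᵢ|G), with per-observation emission
   ½ p(b|a₁) + ½ p(b|a₂), p(b|a) = 1−ē if b = a else ē/3, ambiguous
   observations split equally over their two compatible bases, and ē a
   per-site *average error rate* (mean Phred-implied error, clamped to
   [10⁻⁴, 0.5]). The prior is SOAPsnp-style (reference homozygote 0.9985,
   heterozygote-with-reference 10⁻³, non-reference homozygote 5×10⁻⁴,
   transitions ×4, renormalised). The maximum-posterior genotype is called;
   GQ = −10·log₁₀(1−posterior), `LowQual` below 10, `LowFreq` for
   low-frequency homozygous-alternate calls.

4. **Outputs.** VCF 4.2 (variant sites only, with strand-resolved allele
   depths `ADF`/`ADR`) and per-context (CpG/CHG/CHH) methylation tables
   computed from the genotype-corrected sequence: level = W_C/(W_C+W_T) at
   Watson cytosines, C_G/(C_G+C_A) at Crick cytosines.

A seeded simulator (`bs_simulate()`) generates diploid genomes with planted
SNPs, context-specific methylation, bisulfite conversion and sequencing
error, plus truth VCF/TSV — every claim in the test suite is checked against
it. See the methods vignette (`vignettes/bsvar-methods.Rmd`) for the model
in full.

## Worked example

```r
library(bsvar)

# 10 kb diploid genome, ~10 planted SNPs, 20x bisulfite reads
sim <- bs_simulate(sim_params(genome_length = 10000, snp_rate = 0.001),
                   seed = 42, out_prefix = file.path(tempdir(), "demo"))

res <- bs_call(sim$paths[["sam"]], sim$paths[["ref"]])
tidy(res)
#> # A tibble: 10 × 10
#>    chrom   pos ref   genotype depth   err posterior phred_quality filter
#>  1 chr1   1846 C     CG          21  0.01     1.000            96 PASS
#>  4 chr1   3895 C     AC          13  0.01     0.998            27 PASS
#>  6 chr1   4423 G     GT          20  0.01     1.000            92 PASS
#> 10 chr1   9158 C     TT          20  0.01     0.969            15 PASS
#> # ... (8 PASS calls, 2 LowQual)

glance(res)
#> # A tibble: 1 × 7
#>   n_reads n_admitted n_candidates n_variants n_pass mean_gq n_meth_records
#> 1    2000       1867           24         10      8      43           4965

evaluate_calls(res, sim)$summary
#> # A tibble: 1 × 8
#>   n_called n_truth    tp    fp    fn   fpr   fnr concordance
#> 1        8       8     8     0     0     0     0           1
```

The call at chr1:9158 is the interesting one: the reference is C, Watson
reads show only T — indistinguishable from an unmethylated cytosine — but
Crick reads show T rather than C, so the site is called a true `TT`
homozygote. Conversely, thousands of fully converted cytosines elsewhere
produce no call at all. The eight PASS calls recover all eight planted SNPs
with their exact genotypes (`concordance 1`); the two `LowQual` records are
borderline two-read signals the FILTER column marks for exclusion.
Methylation comes out per context:

```r
dplyr::filter(res$meth, context == "CpG", total_count >= 8)
#>   chrom   pos strand context meth_count total_count level genotype_corrected
#> 1 chr1    117 -      CpG             13          13 1     FALSE
#> 2 chr1    121 -      CpG             11          13 0.846 FALSE
#> ...
```

levels scattering around the planted CpG level of 0.8 with binomial noise.
`autoplot(res)` plots GQ against depth by filter status;
`plot_methylation_levels(res)` shows the level distributions per context.

A command-line wrapper with `call` / `simulate` / `evaluate` subcommands and
the usual flag set (`--minmapq`, `--minhetfreq`, `--mincover`, ...) is
installed at `inst/scripts/bsvar.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/bsvar.R", package="bsvar"))')" \
  call --fa ref.fa --input sorted.bam --output out.vcf --methcg cg.tsv
```

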