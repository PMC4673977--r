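---
title: "Calling SNPs in bisulfite sequencing data: the bsvar model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling SNPs in bisulfite sequencing data: the bsvar model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sodium bisulfite converts unmethylated cytosines to uracil, read as thymine
after PCR. In the resulting libraries (WGBS, RRBS) a genuine C→T SNP is
indistinguishable, on the strand carrying the cytosine, from an unmethylated
cytosine: both present as T. The same confusion arises on the opposite
original strand as G→A. Because the two original strands convert
independently, the resolution is to treat them independently: a Watson-strand
read showing T at a reference C says nothing by itself, but Crick-strand reads
at the same position still read the unconverted G/C pair and discriminate a
true variant from conversion. `bsvar` implements this strand-separated caller
end to end: pileup, candidate screen, Bayesian diploid genotyping, VCF output
and genotype-corrected methylation extraction, together with a read simulator
that provides ground truth for every test in the package.

## The dynamic-matrix pileup

Alignments are consumed one chromosome at a time. For the current chromosome
a matrix of per-position vectors is allocated: for each of the eight
observation classes (Watson A/C/G/T, Crick A/C/G/T) an integer read count and
a summed Phred quality. The matrix is filled from admitted reads, genotyped,
and released before the next chromosome is touched, so peak memory follows
the largest chromosome rather than the genome. All bases are recorded in
reference orientation, i.e. exactly as they appear in the SAM `SEQ` field;
the bisulfite strand of origin comes from the aligner's `ZS` (BSMAP) or `XG`
(Bismark) tag, falling back to the FLAG reverse bit (inverted for
second-of-pair mates) when neither tag is present. Under this convention the
two conversion-ambiguous classes are Watson-T (genomic T or converted C) and
Crick-A (genomic A or converted G); Crick reads at a reference C show C, so
C-versus-T discrimination rests on the Crick strand and G-versus-A
discrimination on the Watson strand.

Read admission requires a primary, non-duplicate, non-QC-fail alignment with
mapping quality ≥ 20 and a bisulfite-adjusted mismatch rate ≤ 0.02 of aligned
length — mismatches are counted after excusing Watson C→T and Crick G→A
differences, which are expected chemistry, not error. Bases below the Phred
floor (15, Phred+33 input) and N bases are never counted, and overlapping
mate pairs contribute each position once, keeping the higher-quality base, so
one molecule is never double-counted.

## Candidate screen

A position becomes a candidate when its retained depth lies in
`[min_cover, max_cover]` (defaults 10 and 1000) and some non-reference allele
reaches effective frequency ≥ 0.1 with at least 2 effective observations.
Effective counts exclude the two ambiguous classes entirely:

* eff(A) = Watson A, eff(T) = Crick T (single-strand support by necessity),
* eff(C) = Watson C + Crick C, eff(G) = Watson G + Crick G,

and freq(X) = eff(X) / Σ eff. Excluding, rather than fractionally splitting,
ambiguous observations in the frequency is the conservative choice: a wave of
converted cytosines can never manufacture a C/T candidate on its own. The
ambiguous classes re-enter in the genotype likelihood, where they are handled
probabilistically.

## The approximate Bayesian genotyper

At each candidate the posterior over the ten diploid genotypes is
`P(G|D) ∝ P(G) · Π_i P(D_i|G)`, evaluated in log space.

**Emission.** For an unambiguous observation of base *b*,
`P(b | {a1,a2}) = ½ p(b|a1) + ½ p(b|a2)` with `p(b|a) = 1−ē` if `b = a`, else
`ē/3`. An ambiguous observation is split equally over its two compatible
bases: a Watson T emits `½ [p(C|a) + p(T|a)]` per allele, a Crick A
`½ [p(A|a) + p(G|a)]`. This "wildcard" treatment needs no methylation
estimate inside the genotype model. Every emission is linear in `ē`, which
the implementation exploits by precomputing the two 8×10 coefficient
matrices once and evaluating whole chromosomes of candidates as matrix
operations.

**Average error rate.** Instead of per-read error modelling, one `ē` per
site: each observation class contributes `10^(−Q̄/10)` at its mean quality
`Q̄ = qual_sum/count`, averaged over observations and clamped to
`[10⁻⁴, 0.5]`. The clamp floor keeps a Q60 base from claiming impossible
certainty; the ceiling keeps the emission model proper.

**Prior.** A SOAPsnp-style prior per reference base: 0.9985 for the
reference homozygote, 0.001 for each heterozygote containing the reference,
0.0005 for each non-reference homozygote, and `het·hom = 5×10⁻⁷` for
heterozygotes of two non-reference alleles (the spec of the prior names only
the first three masses; the product form is the natural completion and its
exact value is immaterial — see the robustness property below). Genotypes
containing the transition partner of the reference are up-weighted ×4, then
the ten weights are renormalised. At depth > 10 the argmax is essentially
prior-free: the test suite verifies that the called genotype is identical
across reference-homozygote masses {0.99, 0.9985, 0.999} for ≥ 99% of sites.

**Call.** The maximum-posterior genotype is kept; exact ties break toward a
genotype containing the reference, then lexicographically. Quality is
`round(−10·log10(1−posterior))` capped at 1000; calls below quality 10 are
flagged `LowQual`, homozygous-alternate calls whose alternate frequency is
below 0.85 are flagged `LowFreq`. A site where both strands are ambiguous
(Watson T plus Crick A) is genuinely unresolvable: the equal-split emission
puts the likelihood maximum on heterozygotes pairing one {C,T}- with one
{A,G}-compatible allele at posterior ≈ 0.5, so such sites surface as
`LowQual` records rather than confident C/T or G/A calls, and the CC/TT
ordering within the posterior is purely the prior's.

## Methylation extraction

After genotyping, homozygous-alternate calls are substituted into the
reference to form the corrected sequence; methylation is then read from the
conversion-informative strand only. A site whose genotype contains C on
Watson is scored `W_C / (W_C + W_T)`, a site with G (a Crick-strand cytosine)
`C_G / (C_G + C_A)`; the two strands of a CpG are reported as separate
records. Context (CpG / CHG / CHH) is computed from the corrected sequence —
two bases downstream on the cytosine's own strand — so a called SNP can
create or destroy a context. Sites whose genotype removes the cytosine yield
no record; sites with zero informative depth are omitted rather than written
as NA rows; cytosines within 2 bp of a chromosome end keep an undetermined
(`NA`) context. Heterozygous C sites are still reported (flagged
`genotype_corrected`), but their level mixes genomic T with conversion and
cannot be deconvolved from counts alone — a known limitation shared by
count-ratio extractors.

## The simulator

`bs_simulate()` generates the package's study conditions: a uniform-random
ACGT genome (default 10 kb), SNPs planted at 0.001/bp with
transition:transversion ratio 2, half heterozygous (alternate on one
haplotype); per-context methylation levels CpG 0.8, CHG 0.05, CHH 0.02;
single-end 100 bp reads at mean depth 20 drawn uniformly from both
haplotypes and strands; unmethylated cytosines read as T (Watson) or, in
reference orientation, G as A (Crick) with conversion probability 0.99;
uniform sequencing error 0.01 applied after conversion with constant Phred
`round(−10·log10(error))`. Defaults are desk-scale stand-ins for the RRBS
setting the method targets: 20× is typical covered-CpG depth, 1% error is
conservative Illumina quality (Q20), 99% conversion is routine chemistry,
and 0.001/bp approximates human heterozygosity. Reads carry `XG` and `ZS`
tags and are written as coordinate-sorted SAM with FASTA + `.fai` and truth
VCF/TSV, all byte-deterministic under a fixed seed.

What the simulator deliberately omits: RRBS fragment selection, PCR
duplicates, quality decay along reads, indels, mapping error and incomplete-
conversion clustering. Passing tests therefore demonstrate correctness of
the counting, the model arithmetic and the strand logic — not performance on
real libraries, where alignment artefacts dominate.

## What the tests pin down, and the sizes used

The suite (and `scripts/acceptance.R`, which recomputes the same quantities
from scratch) checks, at sizes chosen to keep a laptop run comfortable:

* *Oracle equivalence* — the vectorised caller reproduces a brute-force
  enumeration of prior × product-likelihood (plain arithmetic, observations
  expanded one by one) over 10,000 random profiles of depth ≤ 50: argmax
  identical (exact numerical posterior ties excepted — two arithmetic paths
  cannot order a true tie) and posteriors within 10⁻⁹.
* *Bisulfite safety* — on a SNP-free 10 kb / 20× simulation, no C/T or G/A
  variant is called at any cytosine with ≥ 10 opposite-strand reads.
* *Recovery* — pooled over three seeded simulations with planted SNPs,
  genotype concordance ≥ 99% at resolvable truth sites, and every covered
  homozygous C→T (and G→A) SNP is called as the variant, never as the
  reference cytosine. "Resolvable" means every truth allele keeps ≥ 3
  effective observations: with a realistic het prior (~10⁻³) and a per-read
  likelihood ratio of ~10², two effective reads cannot overcome the
  reference prior while three can, so the 2-read boundary is undecidable for
  any Bayes caller, not an implementation property.
* *Conservation and normalisation* — pileup counts equal the number of
  quality-passing aligned bases exactly (integer identity); posteriors and
  effective frequencies sum to 1 within 10⁻⁹; the 0.1 frequency gate keeps a
  2/10 minor allele and drops 1/20. The pileup is independently cross-checked
  against `Rsamtools::pileup` counts.
* *Round-trips* — the VCF re-parses (vcfR) with identical
  CHROM/POS/REF/ALT/GT, REF always equals the reference base at POS, and at
  CC-genotype CpGs ≥ 99% of levels lie within 3 binomial standard errors of
  the planted 0.8 (with hundreds of discrete binomial sites, 3·SE coverage
  cannot be asserted for literally every site).

One property is knowingly red and documented as such: the joint end-to-end
gate "miss rate ≤ 0.1 and false-call rate ≤ 0.05" at 20×. Counting the final
(PASS) set, false calls are rare (~2%) but the miss rate is ~0.2, because
bisulfite ambiguity halves the informative depth at transition SNPs: a
homozygous G→A at a reference A is supported only by Watson reads, and at a
coverage dip four informative reads give posterior ≈ 0.89 — a correct call
flagged `LowQual` by one quality point. Counting filtered records as called,
the miss rate is ~0.09–0.10 but the false-call rate rises to ~0.17, the very
records `FILTER` exists to mark. No threshold was adjusted to trade one
bound against the other; `evaluate_calls()` defaults to final-set semantics
(`pass_only = TRUE`) because that is the set a user consumes.

## Numerical and design notes

* Coordinates are 1-based inside R structures (matching R indexing and VCF);
  the SAM/VCF/TSV writers and readers agree on this throughout.
* Likelihoods are evaluated as `counts · log(A₀ + ē·B)`; with `ē ≥ 10⁻⁴`
  every emission is strictly positive, so no log(0) path exists and
  underflow is handled by the log-sum-exp normalisation.
* The genotype set is fixed in lexicographic order (AA … TT); all tie-breaks
  and VCF ALT orderings derive from it, making runs byte-deterministic.
* Reads are loaded per file and split by chromosome; only the pileup
  matrices — the memory-relevant object at scale — follow the
  allocate/fill/call/release cycle.
* The candidate screen requires nonzero effective depth; a site observed
  only through ambiguous classes can therefore never become a candidate,
  which is the desired behaviour for fully converted, Watson-only-covered
  cytosines.
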