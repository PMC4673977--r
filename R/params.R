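#' Read- and site-level filter parameters
#'
#' Thresholds applied when admitting alignments into the pileup and when
#' screening candidate variant sites. Candidate discovery keeps a non-reference
#' allele when its bisulfite-effective frequency is at least `min_het_freq`
#' (default 0.1) and it is supported by at least `min_alt_reads` effective
#' observations; `min_hom_freq` governs the `LowFreq` FILTER flag on
#' homozygous-alternate calls, not discovery.
#'
#' @param min_map_quality Minimum mapping quality for a read to be admitted.
#' @param min_base_quality Minimum Phred base quality for an observation to be
#'   counted (Phred scale; qualities are decoded from Phred+33 input).
#' @param max_mismatch_rate Maximum fraction of aligned bases that may mismatch
#'   the reference, after excluding bisulfite conversions (Watson C→T,
#'   Crick G→A).
#' @param min_het_freq Minimum effective allele frequency for a non-reference
#'   allele to seed a candidate site.
#' @param min_hom_freq Minimum alternate-allele frequency below which a
#'   homozygous-alternate call is flagged `LowFreq`.
#' @param min_cover,max_cover Retained-observation depth range for a site to be
#'   genotyped.
#' @param min_alt_reads Minimum effective observation count for a candidate
#'   allele.
#'
#' @return A `bs_filter_params` list.
#' @export
#' @examples
#' filter_params(min_cover = 5)
filter_params <- function(min_map_quality = 20L,
                          min_base_quality = 15L,
                          max_mismatch_rate = 0.02,
                          min_het_freq = 0.1,
                          min_hom_freq = 0.85,
                          min_cover = 10L,
                          max_cover = 1000L,
                          min_alt_reads = 2L) {
  if (!(min_het_freq >= 0 && min_het_freq <= min_hom_freq && min_hom_freq <= 1)) {
    bs_abort("need 0 <= min_het_freq <= min_hom_freq <= 1", "bsvar_usage_error")
  }
  if (min_cover > max_cover) {
    bs_abort("min_cover must not exceed max_cover", "bsvar_usage_error")
  }
  structure(
    list(
      min_map_quality = as.integer(min_map_quality),
      min_base_quality = as.integer(min_base_quality),
      max_mismatch_rate = max_mismatch_rate,
      min_het_freq = min_het_freq,
      min_hom_freq = min_hom_freq,
      min_cover = as.integer(min_cover),
      max_cover = as.integer(max_cover),
      min_alt_reads = as.integer(min_alt_reads)
    ),
    class = "bs_filter_params"
  )
}

#' Prior over the ten diploid genotypes
#'
#' SOAPsnp-style genotype prior: mass for the reference homozygote, for
#' heterozygotes containing the reference allele, and for non-reference
#' homozygotes; heterozygotes of two non-reference alleles receive
#' `het_with_ref * non_ref_hom`. Genotypes containing the transition partner of
#' the reference base are up-weighted by `ts_tv_weight`, and the ten weights
#' are renormalised to sum to one.
#'
#' @param ref_hom Prior mass of the reference homozygote.
#' @param het_with_ref Prior mass of each heterozygote containing the
#'   reference allele.
#' @param non_ref_hom Prior mass of each non-reference homozygote.
#' @param ts_tv_weight Multiplicative weight (>= 1) for genotypes containing
#'   the transition allele of the reference.
#'
#' @return A `bs_genotype_prior` list.
#' @export
#' @examples
#' prior_vector("A", genotype_prior())
genotype_prior <- function(ref_hom = 0.9985,
                           het_with_ref = 0.001,
                           non_ref_hom = 0.0005,
                           ts_tv_weight = 4.0) {
  if (ts_tv_weight < 1) bs_abort("ts_tv_weight must be >= 1", "bsvar_usage_error")
  structure(
    list(
      ref_hom = ref_hom,
      het_with_ref = het_with_ref,
      non_ref_hom = non_ref_hom,
      ts_tv_weight = ts_tv_weight
    ),
    class = "bs_genotype_prior"
  )
}

#' Simulation parameters
#'
#' Study conditions for the bundled bisulfite-read simulator: a uniform-random
#' diploid genome with SNPs planted at `snp_rate` (transition:transversion
#' ratio 2), context-specific methylation levels, single-end reads drawn
#' uniformly from both haplotypes and both original strands, bisulfite
#' conversion of unmethylated cytosines at `conversion_rate`, and uniform
#' sequencing error at `error_rate` with constant Phred qualities
#' `round(-10*log10(error_rate))`.
#'
#' @param genome_length Genome length in bp.
#' @param snp_rate Per-bp probability of a planted SNP.
#' @param het_fraction Fraction of planted SNPs that are heterozygous.
#' @param methylation_by_context Named levels for CpG, CHG and CHH cytosines.
#' @param conversion_rate Probability an unmethylated cytosine reads as T.
#' @param depth Mean sequencing coverage.
#' @param read_length Read length in bp.
#' @param error_rate Per-base sequencing error probability.
#' @param chrom Chromosome name used in all outputs.
#'
#' @return A `bs_sim_params` list.
#' @export
#' @examples
#' sim_params(genome_length = 2000, depth = 10)
sim_params <- function(genome_length = 10000L,
                       snp_rate = 0.001,
                       het_fraction = 0.5,
                       methylation_by_context = c(CpG = 0.8, CHG = 0.05, CHH = 0.02),
                       conversion_rate = 0.99,
                       depth = 20,
                       read_length = 100L,
                       error_rate = 0.01,
                       chrom = "chr1") {
  probs <- c(snp_rate, het_fraction, methylation_by_context, conversion_rate, error_rate)
  if (any(probs < 0 | probs > 1)) {
    bs_abort("all rates must lie in [0, 1]", "bsvar_usage_error")
  }
  if (depth <= 0 || genome_length < read_length) {
    bs_abort("need depth > 0 and genome_length >= read_length", "bsvar_usage_error")
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      snp_rate = snp_rate,
      het_fraction = het_fraction,
      methylation_by_context = methylation_by_context,
      conversion_rate = conversion_rate,
      depth = depth,
      read_length = as.integer(read_length),
      error_rate = error_rate,
      chrom = chrom
    ),
    class = "bs_sim_params"
  )
}
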