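#' Simulation configuration
#'
#' Parameters of the synthetic transposon-mutagenesis study. The generator
#' emulates the hallmarks of a real insertion screen in a genome-reduced
#' bacterium: contrasting insertion densities in essential versus dispensable
#' regions, low-read noise insertions inside essential genes, a bimodal
#' reads-per-insertion distribution separating the gold sets, serial-passage
#' decay of essential-gene insertion reads, optional insertion depletion at
#' G/C-rich quadruplets, and expression time courses with planted
#' correlated/anti-correlated antisense ncRNA--ORF pairs.
#'
#' @param seed Master RNG seed; every generator derives its stream from it.
#' @param genome_length Genome size in bp (>= 1000).
#' @param gc_content Genome G+C fraction in `[0, 1]`.
#' @param n_orfs,n_smorfs,n_ncrnas,n_convrnas Feature counts. smORFs encode
#'   proteins of fewer than 100 residues.
#' @param frac_essential Fraction of ORFs (and smORFs) that are essential.
#' @param frac_fitness Fraction of ORFs that are fitness genes, generated as
#'   mixed-domain proteins carrying one essential and one dispensable domain.
#' @param n_essential_intergenic Number of essential non-transcribed segments
#'   (oriC-like structural elements) planted between genes.
#' @param insertion_rate_ne Insertions per bp in non-essential sequence.
#' @param noise_rate_e Insertions per bp inside essential sequence (reads from
#'   the low-count noise distribution).
#' @param reads_ne_mean,reads_e_mean Expected reads per insertion for the two
#'   classes; must satisfy `reads_ne_mean > reads_e_mean > 0` so that
#'   threshold calibration has separable distributions to work with.
#' @param read_dispersion Negative-binomial overdispersion `phi`
#'   (`Var = mu + phi * mu^2`); 0 gives Poisson counts.
#' @param passage_days Numeric day labels of the serial-passage samples.
#' @param decay_halflife_days Half-life (days) of the expected read count of
#'   insertions inside essential sequence, measured from the first passage
#'   day; `Inf` disables decay. Non-essential read counts are stationary.
#' @param quadruplet_bias Multiplier in `[0, 1]` applied to the insertion
#'   probability at positions whose surrounding 4-mer has >= 3 G/C bases.
#' @param n_timepoints Number of expression time points (>= 3).
#' @param frac_anticorrelated Fraction of antisense ncRNA--ORF pairs planted
#'   anti-correlated (the rest are planted correlated).
#' @param anticorr_e_weight Odds-style multiplier coupling anti-correlation to
#'   host-ORF essentiality: the anti-correlation probability for ncRNAs over
#'   essential hosts is `min(0.95, frac_anticorrelated * anticorr_e_weight)`.
#'   1 means sign and essentiality are independent.
#' @param expression_noise_sd Gaussian noise SD added to every expression
#'   value (both members of a planted pair), so a planted pair's population
#'   correlation is `-1/(1 + sd^2)` (about -0.9 at the default 0.3).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_content = 0.40,
                       n_orfs = 60L,
                       n_smorfs = 6L,
                       n_ncrnas = 20L,
                       n_convrnas = 6L,
                       frac_essential = 0.45,
                       frac_fitness = 0.10,
                       n_essential_intergenic = 2L,
                       insertion_rate_ne = 0.02,
                       noise_rate_e = 0.002,
                       reads_ne_mean = 60,
                       reads_e_mean = 3,
                       read_dispersion = 0.5,
                       passage_days = c(4, 8, 12),
                       decay_halflife_days = 2,
                       quadruplet_bias = 1,
                       n_timepoints = 10L,
                       frac_anticorrelated = 0.5,
                       anticorr_e_weight = 1,
                       expression_noise_sd = 0.3) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_content = gc_content, n_orfs = as.integer(n_orfs),
              n_smorfs = as.integer(n_smorfs), n_ncrnas = as.integer(n_ncrnas),
              n_convrnas = as.integer(n_convrnas),
              frac_essential = frac_essential, frac_fitness = frac_fitness,
              n_essential_intergenic = as.integer(n_essential_intergenic),
              insertion_rate_ne = insertion_rate_ne, noise_rate_e = noise_rate_e,
              reads_ne_mean = reads_ne_mean, reads_e_mean = reads_e_mean,
              read_dispersion = read_dispersion,
              passage_days = as.numeric(passage_days),
              decay_halflife_days = decay_halflife_days,
              quadruplet_bias = quadruplet_bias,
              n_timepoints = as.integer(n_timepoints),
              frac_anticorrelated = frac_anticorrelated,
              anticorr_e_weight = anticorr_e_weight,
              expression_noise_sd = expression_noise_sd)
  fracs <- c("gc_content", "frac_essential", "frac_fitness", "quadruplet_bias",
             "frac_anticorrelated")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$genome_length < 1000) stop("genome_length must be >= 1000", call. = FALSE)
  if (cfg$insertion_rate_ne < 0 || cfg$noise_rate_e < 0 ||
      cfg$read_dispersion < 0 || cfg$expression_noise_sd < 0)
    stop("rates, dispersion and noise SD must be >= 0", call. = FALSE)
  if (!(cfg$reads_ne_mean > cfg$reads_e_mean && cfg$reads_e_mean > 0))
    stop("need reads_ne_mean > reads_e_mean > 0 (separable read distributions)",
         call. = FALSE)
  if (length(cfg$passage_days) < 1L || any(duplicated(cfg$passage_days)))
    stop("passage_days must be distinct day labels", call. = FALSE)
  if (cfg$decay_halflife_days <= 0) stop("decay_halflife_days must be > 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic transposon-screen configuration\n")
  cat(sprintf("  genome: %d bp, GC %.2f; %d ORFs, %d smORFs, %d ncRNAs\n",
              x$genome_length, x$gc_content, x$n_orfs, x$n_smorfs, x$n_ncrnas))
  cat(sprintf("  essentiality: %.0f%% E, %.0f%% F (mixed-domain)\n",
              100 * x$frac_essential, 100 * x$frac_fitness))
  cat(sprintf("  insertions: NE %.4g/bp, E noise %.4g/bp; reads %g vs %g (phi %.2g)\n",
              x$insertion_rate_ne, x$noise_rate_e, x$reads_ne_mean,
              x$reads_e_mean, x$read_dispersion))
  cat(sprintf("  passages: days %s, E-read half-life %g d\n",
              paste(x$passage_days, collapse = "/"), x$decay_halflife_days))
  invisible(x)
}
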