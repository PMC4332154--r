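#' Simulate transposon insertion libraries over serial passages
#'
#' Places insertions on the simulated genome -- uniformly at
#' `insertion_rate_ne` per bp in dispensable sequence, and at the much lower
#' `noise_rate_e` inside ground-truth essential sequence (dead-clone noise) --
#' and draws per-day read counts. Non-essential insertion reads are negative
#' binomial with stationary mean `reads_ne_mean`; essential-insertion read
#' means decay exponentially with half-life `decay_halflife_days` from the
#' first passage day, emulating the washout of lethal insertions over serial
#' passages. When `quadruplet_bias < 1`, positions whose surrounding 4-mer
#' (bases p-1..p+2) contains >= 3 G/C bases have their insertion probability
#' multiplied by it. Sites whose drawn read count is zero on a given day are
#' absent from that day's table.
#'
#' @param sim A [simulate_genome()] result.
#' @param config A [sim_config()]; defaults to `sim$config`.
#' @return Named list of insertion tables (one per day, names = day labels).
#'   Each table is a data.frame `position`, `orientation`, `reads`, `sample`,
#'   `day` with attributes `genome_id` and `G`.
#' @export
simulate_insertions <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(sub_seed(config$seed, 2))
  G <- nchar(sim$genome)
  ess <- rep(FALSE, G)
  if (nrow(sim$essential_regions))
    for (i in seq_len(nrow(sim$essential_regions)))
      ess[sim$essential_regions$start[i]:sim$essential_regions$end[i]] <- TRUE
  rate <- ifelse(ess, config$noise_rate_e, config$insertion_rate_ne)
  if (config$quadruplet_bias < 1) {
    rate[gc_rich_quadruplet(sim$genome)] <- rate[gc_rich_quadruplet(sim$genome)] *
      config$quadruplet_bias
  }
  pos <- which(runif(G) < pmin(rate, 1))
  orient <- sample(c("+", "-"), length(pos), replace = TRUE)
  is_e <- ess[pos]
  days <- sort(config$passage_days)
  phi <- config$read_dispersion
  out <- lapply(days, function(d) {
    decay <- if (is.finite(config$decay_halflife_days))
      2^(-(d - days[1]) / config$decay_halflife_days) else 1
    mu <- ifelse(is_e, config$reads_e_mean * decay, config$reads_ne_mean)
    reads <- if (phi > 0) rnbinom(length(pos), size = 1 / phi, mu = mu)
             else stats::rpois(length(pos), mu)
    keep <- reads >= 1L
    tab <- data.frame(position = pos[keep], orientation = orient[keep],
                      reads = as.integer(reads[keep]), sample = "sim",
                      day = d, stringsAsFactors = FALSE)
    attr(tab, "genome_id") <- "sim"
    attr(tab, "G") <- G
    tab
  })
  names(out) <- as.character(days)
  out
}

# Logical mask: positions whose surrounding 4-mer (p-1 .. p+2, circular) has
# >= 3 G or C bases. The same convention is used by quadruplet_bias().
gc_rich_quadruplet <- function(genome) {
  s <- as.integer(strsplit(genome, "")[[1]] %in% c("G", "C"))
  G <- length(s)
  idx <- function(k) s[((seq_len(G) - 1 + k) %% G) + 1]
  q <- idx(-1) + idx(0) + idx(1) + idx(2)
  q >= 3
}

#' Simulate transposon-junction reads
#'
#' One FASTQ record per supporting read of each insertion site: the inverted
#' repeat tag followed by `read_length` bp of genomic flank starting at the
#' insertion coordinate in the site's recorded orientation (minus-strand
#' flanks read leftwards and are reverse-complemented). The genome is treated
#' as circular for flank extraction.
#'
#' @param table Insertion table (one day).
#' @param genome Genome sequence (character) or a [simulate_genome()] result.
#' @param ir_tag Inverted-repeat prefix sequence.
#' @param read_length Genomic flank length in bp.
#' @return data.frame `id`, `seq`, `qual` (constant quality), one row per read.
#' @export
simulate_reads <- function(table, genome, ir_tag = "ACTTGTGGCC", read_length = 30L) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  assert_insertion_table(table)
  G <- nchar(genome)
  if (read_length < 1L || read_length + nchar(ir_tag) > min(G, 100000L))
    stop("read_length + |ir_tag| out of practical range", call. = FALSE)
  if (nrow(table) == 0L)
    return(data.frame(id = character(), seq = character(), qual = character()))
  rows <- rep(seq_len(nrow(table)), table$reads)
  flank <- vapply(seq_len(nrow(table)), function(i) {
    p <- table$position[i]
    if (table$orientation[i] == "+") circ_substr(genome, p, read_length, G)
    else revcomp(circ_substr(genome, p - read_length + 1L, read_length, G))
  }, character(1))
  rep_idx <- sequence(table$reads)
  data.frame(
    id = sprintf("site%07d%s_r%d", table$position[rows], table$orientation[rows],
                 rep_idx),
    seq = paste0(ir_tag, flank[rows]),
    qual = strrep("I", read_length + nchar(ir_tag)),
    stringsAsFactors = FALSE)
}

#' Simulate an expression time course with planted antisense pairs
#'
#' Builds a feature-by-timepoint expression matrix for all ORFs, smORFs and
#' ncRNAs. Each coding feature gets an independent standard-normal profile.
#' Every antisense ncRNA is planted against its host ORF: with probability
#' `frac_anticorrelated` (raised by `anticorr_e_weight` for essential hosts)
#' its noiseless profile is the negative of the host's, otherwise an exact
#' copy. Gaussian noise of SD `expression_noise_sd` is then added to every
#' value, so a planted pair's population correlation is `+/- 1/(1 + sd^2)`
#' (about 0.9 in magnitude at the default 0.3) and is exactly `+/- 1` at
#' `sd = 0`. All other feature pairs are independent.
#'
#' @param sim A [simulate_genome()] result.
#' @param config A [sim_config()]; defaults to `sim$config`.
#' @return Numeric matrix (features x timepoints, columns `t1..tn`) with
#'   attribute `pairs`: data.frame `ncrna`, `orf`, `planted_sign`
#'   (`"anti"`/`"corr"`).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_genome"))
  if (config$n_timepoints < 3L)
    stop("need at least 3 timepoints (correlation is degenerate below that)",
         call. = FALSE)
  set.seed(sub_seed(config$seed, 3))
  ann <- sim$annotation
  coding <- ann[ann$type %in% c("ORF", "smORF"), , drop = FALSE]
  ncr <- ann[ann$type == "ncRNA", , drop = FALSE]
  Tn <- config$n_timepoints
  base <- matrix(rnorm(nrow(coding) * Tn), nrow = nrow(coding),
                 dimnames = list(coding$id, paste0("t", seq_len(Tn))))
  pairs <- NULL
  ncr_base <- matrix(0, nrow = nrow(ncr), ncol = Tn,
                     dimnames = list(ncr$id, paste0("t", seq_len(Tn))))
  if (nrow(ncr)) {
    host <- antisense_host(ncr, coding)
    for (i in seq_len(nrow(ncr))) {
      if (is.na(host[i])) { ncr_base[i, ] <- rnorm(Tn); next }
      p_anti <- if (coding$truth[match(host[i], coding$id)] == "E")
        min(0.95, config$frac_anticorrelated * config$anticorr_e_weight)
      else config$frac_anticorrelated
      sgn <- if (runif(1) < p_anti) -1 else 1
      ncr_base[i, ] <- sgn * base[host[i], ]
      pairs <- rbind(pairs, data.frame(
        ncrna = ncr$id[i], orf = host[i],
        planted_sign = if (sgn < 0) "anti" else "corr", stringsAsFactors = FALSE))
    }
  }
  expr <- rbind(base, ncr_base)
  expr <- expr + rnorm(length(expr), sd = config$expression_noise_sd)
  attr(expr, "pairs") <- pairs %||% data.frame(ncrna = character(),
                                               orf = character(),
                                               planted_sign = character())
  expr
}

# Host ORF/smORF overlapped on the opposite strand by each ncRNA (NA if none).
antisense_host <- function(ncr, coding) {
  vapply(seq_len(nrow(ncr)), function(i) {
    hit <- coding$start <= ncr$end[i] & coding$end >= ncr$start[i] &
      coding$strand != ncr$strand[i]
    if (any(hit)) {
      ov <- pmin(coding$end[hit], ncr$end[i]) - pmax(coding$start[hit], ncr$start[i])
      coding$id[hit][which.max(ov)]
    } else NA_character_
  }, character(1))
}
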