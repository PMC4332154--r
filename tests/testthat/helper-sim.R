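# Shared fixtures and independent oracles, built in code at test time.

# Well-separated benchmark: dense insertions in dispensable sequence, sparse
# low-read noise in essential sequence, read means separated 30-fold.
well_separated_config <- function(seed, genome_length = 200000L,
                                  noise_rate_e = 5e-4) {
  sim_config(seed = seed, genome_length = genome_length,
             n_orfs = as.integer(120 * genome_length / 200000),
             n_smorfs = as.integer(10 * genome_length / 200000),
             n_ncrnas = as.integer(30 * genome_length / 200000),
             frac_essential = 0.6, frac_fitness = 0.1,
             insertion_rate_ne = 0.05, noise_rate_e = noise_rate_e,
             reads_ne_mean = 100, reads_e_mean = 3)
}

# Calibration benchmark: like the well-separated screen but with the denser
# essential-gene noise typical before selection has removed dying clones, so
# both gold classes carry plenty of insertions for the error curve.
calibration_config <- function(seed, genome_length = 50000L) {
  cfg <- well_separated_config(seed, genome_length, noise_rate_e = 5e-3)
  cfg$passage_days <- 0
  cfg
}

# Independent brute-force oracle: label every base by scanning outward to the
# nearest insertion site in each direction (circular), then average labels
# over the region. Deliberately per-base and loop-based, sharing no interval
# arithmetic with the implementation under test.
oracle_base_labels <- function(positions, G, N, alpha, w, bases = seq_len(G)) {
  occupied <- rep(FALSE, G)
  occupied[positions] <- TRUE
  lab <- rep(NA_character_, G)
  for (b in bases) {
    if (occupied[b]) { lab[b] <- "NE"; next }       # distance 0 <= w
    dl <- 1L
    while (!occupied[((b - 1L - dl) %% G) + 1L]) dl <- dl + 1L
    dr <- 1L
    while (!occupied[((b - 1L + dr) %% G) + 1L]) dr <- dr + 1L
    L <- dl + dr - 1L                                # insertion-free run containing b
    if ((1 - L / G)^N <= alpha) lab[b] <- "E"
    else if (min(dl, dr) <= w) lab[b] <- "NE"
    else lab[b] <- "none"
  }
  lab
}

oracle_score <- function(start, end, positions, G, N, alpha, w) {
  lab <- oracle_base_labels(positions, G, N, alpha, w)[start:end]
  len <- length(lab)
  round_half_up2 <- function(k) ((200 * k + len) %/% (2 * len)) / 100
  p_e <- round_half_up2(sum(lab == "E"))
  p_ne <- round_half_up2(sum(lab == "NE"))
  list(P_E = p_e, P_NE = p_ne)
}

# Insertion table from bare positions (reads constant unless given).
table_from_positions <- function(positions, reads = 50L, G = NA_integer_,
                                 day = 0) {
  n <- length(positions)
  tab <- data.frame(position = as.integer(positions),
                    orientation = rep_len("+", n),
                    reads = as.integer(rep_len(reads, max(n, 0))[seq_len(n)]),
                    sample = rep_len("s1", n), day = rep_len(day, n),
                    stringsAsFactors = FALSE)
  attr(tab, "G") <- as.integer(G)
  attr(tab, "genome_id") <- "toy"
  tab
}

# Toy genome of spec'd layout for score_region worked cases: G = 10,000 and
# exactly 500 sites leaving (a) a 600 bp insertion-free interval around
# 2001..2600, (b) sites every 20 bp across 4001..4200, (c) a short 88 bp
# insertion-free interval 5987..6074, with filler sites spaced well below the
# significance length everywhere else.
toy_sites_10k <- function() {
  manual <- c(2000L, 2601L,
              seq(4001L, 4201L, by = 20L),
              5986L, 6075L)
  blocks <- list(c(1L, 1999L), c(2602L, 3980L), c(4221L, 5985L),
                 c(6076L, 10000L))
  n_fill <- 500L - length(manual)
  lens <- vapply(blocks, function(b) b[2] - b[1] + 1L, integer(1))
  alloc <- round(n_fill * lens / sum(lens))
  alloc[1] <- n_fill - sum(alloc[-1])
  fill <- unlist(lapply(seq_along(blocks), function(i)
    as.integer(round(seq(blocks[[i]][1], blocks[[i]][2],
                         length.out = alloc[i])))))
  sites <- sort(unique(c(manual, fill)))
  stopifnot(length(sites) == 500L)
  sites
}
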