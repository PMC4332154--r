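test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, genome_length = 20000L, n_orfs = 10L,
                    n_smorfs = 2L, n_ncrnas = 5L, n_convrnas = 2L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$domains, b$domains)
  expect_identical(simulate_insertions(a), simulate_insertions(b))
  expect_identical(simulate_expression(a), simulate_expression(b))
})

test_that("simulated genomes honour composition, structure and feasibility", {
  cfg <- sim_config(seed = 2, genome_length = 100000L, gc_content = 0.40)
  sim <- simulate_genome(cfg)
  expect_equal(nchar(sim$genome), 100000L)
  gc <- sum(strsplit(sim$genome, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.40), 0.01)   # binomial bound at this length

  ann <- sim$annotation
  orfs <- ann[ann$type %in% c("ORF", "smORF"), ]
  # non-overlapping ORFs within the genome
  expect_true(all(ann$start >= 1 & ann$end <= 100000))
  o <- orfs[order(orfs$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  # every ORF starts with ATG and ends with a code-4 stop, on its strand
  for (i in sample(nrow(orfs), 10)) {
    s <- substr(sim$genome, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") s <- tnseqr:::revcomp(s)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG"))
    codons <- substring(s, seq(4, nchar(s) - 3, by = 3),
                        seq(6, nchar(s) - 1, by = 3))
    expect_false(any(codons %in% c("TAA", "TAG")))  # TGA is Trp, allowed
  }
  # smORFs encode < 100 residues; every feature has a truth category
  sm <- ann[ann$type == "smORF", ]
  expect_true(all((sm$end - sm$start + 1) / 3 - 1 < 100))
  expect_true(all(ann$truth %in% c("E", "NE", "F")))
  # fitness ORFs carry one essential and one dispensable domain
  f_ids <- ann$id[ann$type == "ORF" & ann$truth == "F"]
  expect_gt(length(f_ids), 0)
  for (id in f_ids) {
    dd <- sim$domains[sim$domains$orf_id == id, ]
    expect_setequal(dd$truth, c("E", "NE"))
  }
  expect_error(simulate_genome(sim_config(seed = 1, genome_length = 2000L,
                                          n_orfs = 500L)),
               "infeasible packing")
})

test_that("insertion placement respects truth masks and Poisson-like rates", {
  cfg <- sim_config(seed = 3, genome_length = 50000L, n_orfs = 25L,
                    noise_rate_e = 0, passage_days = c(0, 6))
  sim <- simulate_genome(cfg)
  tabs <- simulate_insertions(sim)
  ess <- sim$essential_regions
  in_e <- function(p) any(p >= ess$start & p <= ess$end)
  for (tab in tabs)
    expect_false(any(vapply(tab$position, in_e, logical(1))))

  # one large dispensable span: count inside the central 99% Poisson interval
  cfg2 <- sim_config(seed = 4, genome_length = 12000L, n_orfs = 1L,
                     n_smorfs = 0L, n_ncrnas = 0L, n_convrnas = 0L,
                     frac_essential = 0, frac_fitness = 0,
                     n_essential_intergenic = 0L, insertion_rate_ne = 0.05,
                     reads_ne_mean = 1000, reads_e_mean = 1, passage_days = 0,
                     read_dispersion = 0)  # Poisson reads: no zero-truncation loss
  sim2 <- simulate_genome(cfg2)
  tab2 <- simulate_insertions(sim2)[[1]]
  n <- sum(tab2$position >= 1001 & tab2$position <= 11000)
  expect_gte(n, qpois(0.005, 500))
  expect_lte(n, qpois(0.995, 500))
})

test_that("essential-insertion reads decay with the configured half-life", {
  cfg <- sim_config(seed = 6, genome_length = 50000L, n_orfs = 25L,
                    frac_essential = 0.5, noise_rate_e = 0.01,
                    reads_e_mean = 6400, reads_ne_mean = 10000,
                    decay_halflife_days = 2, passage_days = c(0, 12))
  sim <- simulate_genome(cfg)
  tabs <- simulate_insertions(sim)
  ess <- sim$essential_regions
  in_e <- function(tab) {
    f <- vapply(tab$position, function(p) any(p >= ess$start & p <= ess$end),
                logical(1))
    tab[f, ]
  }
  m0 <- mean(in_e(tabs[["0"]])$reads)
  m12 <- mean(in_e(tabs[["12"]])$reads)
  expect_lte(m12, 2^-6 * m0 * 1.5)   # 12 days / half-life 2 = 6 halvings
  # non-essential reads are stationary in expectation
  out_e <- function(tab) tab[!tab$position %in% in_e(tab)$position, ]
  expect_lt(abs(mean(out_e(tabs[["12"]])$reads) /
                  mean(out_e(tabs[["0"]])$reads) - 1), 0.1)
})

test_that("junction reads are constructed per site and invert exactly", {
  g <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  tab <- table_from_positions(c(100L, 301L), reads = c(3L, 2L), G = 500L)
  tab$orientation <- c("+", "-")
  reads <- simulate_reads(tab, g, ir_tag = "ACGTAC", read_length = 25L)
  expect_equal(nrow(reads), 5L)
  expect_true(all(startsWith(reads$seq, "ACGTAC")))
  expect_equal(substr(reads$seq[1], 7, 31), substr(g, 100, 124))
  expect_equal(substr(reads$seq[4], 7, 31),
               tnseqr:::revcomp(substr(g, 277, 301)))
  empty <- simulate_reads(tab[0, ], g, ir_tag = "ACGTAC")
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_reads(tab, g, ir_tag = "ACGTAC", read_length = 9999L),
               "practical range")
})

test_that("expression time courses plant exact antisense pairs", {
  cfg <- sim_config(seed = 8, genome_length = 30000L, n_orfs = 15L,
                    n_ncrnas = 8L, expression_noise_sd = 0,
                    frac_anticorrelated = 1)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim)
  pairs <- attr(expr, "pairs")
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    r <- cor(expr[pairs$ncrna[i], ], expr[pairs$orf[i], ])
    expect_equal(r, -1)   # noiseless anti-correlated construction
  }
  expect_error(simulate_expression(sim, sim_config(seed = 8, n_timepoints = 2L)),
               "3 timepoints")
})

test_that("null correlations among unplanted pairs match the n=10 reference", {
  # |r| > 0.63 is the two-sided 5% point of the null correlation at n = 10;
  # across many independent pairs the exceedance rate should sit near 5%
  set.seed(42)
  hits <- 0L; total <- 0L
  for (s in 1:4) {
    x <- matrix(rnorm(40 * 10), nrow = 40)
    r <- cor(t(x))
    v <- abs(r[upper.tri(r)])
    hits <- hits + sum(v > 0.632)
    total <- total + length(v)
  }
  expect_lt(abs(hits / total - 0.05), 0.04)
})
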