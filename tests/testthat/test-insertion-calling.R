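test_that("IR filtering trims matching prefixes and counts discards", {
  ir <- "ACGTTGCA"
  reads <- c(paste0(ir, "AAAATTTTCCCCGGGG"),       # exact
             paste0("ACGTAGCA", "AAAATTTTCCCCGGGG"), # one substitution
             paste0("TTTTTTTT", "AAAATTTTCCCCGGGG")) # no IR
  f0 <- filter_by_inverted_repeat(reads, ir, max_mismatch = 0)
  expect_equal(f0$flanks, "AAAATTTTCCCCGGGG")
  expect_equal(f0$discarded, 2L)
  f1 <- filter_by_inverted_repeat(reads, ir, max_mismatch = 1)
  expect_equal(length(f1$flanks), 2L)
  expect_equal(f1$discarded, 1L)
  expect_error(filter_by_inverted_repeat(reads, ""), "non-empty")
})

test_that("flank mapping follows the junction coordinate convention", {
  set.seed(9)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  fwd <- substr(g, 1001, 1030)
  rev <- tnseqr:::revcomp(substr(g, 2001, 2030))
  m <- map_flanks(c(fwd, rev), g, k = 20)
  expect_equal(m$calls$position, c(1001L, 2030L))
  expect_equal(m$calls$orientation, c("+", "-"))
  expect_equal(m$ambiguous, 0L)

  # a flank matching a repeated element maps nowhere
  rep_unit <- substr(g, 3001, 3030)
  g2 <- paste0(g, rep_unit, rep_unit)
  m2 <- map_flanks(rep_unit, g2, k = 20)
  expect_equal(nrow(m2$calls), 0L)
  expect_equal(m2$ambiguous, 1L)
  expect_error(map_flanks(fwd, g, k = 10), "ambiguity floor")
})

test_that("collapsing keeps orientations distinct and provenance consistent", {
  calls <- data.frame(position = c(500L, 500L, 500L, 500L),
                      orientation = c("+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  tab <- collapse_sites(calls, G = 1000L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$reads[tab$orientation == "+"], 3L)
  expect_equal(tab$reads[tab$orientation == "-"], 1L)

  empty <- collapse_sites(calls[0, ], G = 1000L)
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(attr(empty, "provenance")), 0L)
})

test_that("read calling round-trips the simulated insertion table exactly", {
  cfg <- sim_config(seed = 10, genome_length = 15000L, n_orfs = 8L,
                    n_smorfs = 2L, n_ncrnas = 4L, n_convrnas = 1L,
                    insertion_rate_ne = 0.01, reads_ne_mean = 20,
                    passage_days = 0)
  sim <- simulate_genome(cfg)
  tab <- simulate_insertions(sim)[[1]]
  ir <- "ACTTGTGGCC"
  reads <- simulate_reads(tab, sim, ir_tag = ir, read_length = 40L)
  called <- call_insertions(reads, sim, ir_tag = ir, max_mismatch = 0, k = 20)
  # bit-exact recovery of (position, orientation, reads)
  want <- tab[order(tab$position, tab$orientation),
              c("position", "orientation", "reads")]
  got <- called[, c("position", "orientation", "reads")]
  rownames(want) <- rownames(got) <- NULL
  expect_identical(got, want)
  # provenance conservation: every read in exactly one bucket
  prov <- attr(called, "provenance")
  expect_equal(prov[["total"]], nrow(reads))
  expect_equal(prov[["total"]],
               prov[["no_ir"]] + prov[["mapped"]] + prov[["ambiguous"]] +
                 prov[["unmapped"]])
})

test_that("mapping is strand-symmetric under genome reflection", {
  cfg <- sim_config(seed = 12, genome_length = 10000L, n_orfs = 5L,
                    n_smorfs = 1L, n_ncrnas = 2L, n_convrnas = 1L,
                    insertion_rate_ne = 0.005, passage_days = 0)
  sim <- simulate_genome(cfg)
  tab <- simulate_insertions(sim)[[1]]
  ir <- "GGCCAATT"
  reads <- simulate_reads(tab, sim, ir_tag = ir, read_length = 40L)
  fl <- filter_by_inverted_repeat(reads, ir)$flanks
  G <- nchar(sim$genome)
  a <- map_flanks(fl, sim$genome, k = 20)$calls
  b <- map_flanks(fl, tnseqr:::revcomp(sim$genome), k = 20)$calls
  a <- a[order(a$position), ]
  b$position <- G - b$position + 1L
  b$orientation <- ifelse(b$orientation == "+", "-", "+")
  b <- b[order(b$position), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("quadruplet bias report is calibrated on unbiased insertions", {
  set.seed(13)
  g <- paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE),
             collapse = "")
  pos <- sample.int(40000, 10000)
  tab <- table_from_positions(pos, G = 40000L)
  qb <- quadruplet_bias(tab, g)
  cls <- tapply(qb$per_quadruplet$observed, qb$per_quadruplet$gc, sum) /
    tapply(qb$per_quadruplet$expected, qb$per_quadruplet$gc, sum)
  expect_true(all(cls > 0.8 & cls < 1.2))
  expect_gt(qb$chisq$p.value, 0.001)
  expect_error(quadruplet_bias(tab[0, ], g), "empty")
  expect_error(quadruplet_bias(tab, "ACG"), "too short")
})

test_that("simulated quadruplet bias is recovered by the report", {
  cfg <- sim_config(seed = 14, genome_length = 100000L, n_orfs = 20L,
                    n_smorfs = 0L, n_ncrnas = 0L, n_convrnas = 0L,
                    frac_essential = 0, frac_fitness = 0,
                    n_essential_intergenic = 0L,
                    insertion_rate_ne = 0.1, reads_ne_mean = 50,
                    passage_days = 0, quadruplet_bias = 0.5)
  sim <- simulate_genome(cfg)
  tab <- simulate_insertions(sim)[[1]]
  qb <- quadruplet_bias(tab, sim$genome)
  # observed/expected for the >=3 G/C class: 0.5 / (1 - 0.5 * f) for class
  # frequency f ~ 0.18 at GC 0.40, i.e. ~0.55
  expect_gt(qb$gc_rich_ratio, 0.4)
  expect_lt(qb$gc_rich_ratio, 0.6)
})
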