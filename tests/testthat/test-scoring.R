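test_that("gap null probability matches the closed form and handles edges", {
  expect_equal(gap_null_probability(100, 10, 1000), 0.9^10, tolerance = 1e-12)
  expect_equal(gap_null_probability(0, 57, 1000), 1)
  expect_equal(gap_null_probability(1000, 3, 1000), 0)
  expect_equal(gap_null_probability(123, 0, 1000), 1)
  expect_error(gap_null_probability(1001, 3, 1000), "L must")
  expect_error(gap_null_probability(-1, 3, 1000), "L must")
  expect_error(gap_null_probability(10, -2, 1000), "N must")
})

test_that("gap null probability is monotone non-increasing in L and N", {
  set.seed(7)
  for (i in 1:20) {
    G <- sample(1000:50000, 1)
    N <- sample(5:200, 1)
    L <- sort(sample(0:G, 25))
    p <- gap_null_probability(L, N, G)
    expect_true(all(diff(p) <= 1e-15))
    expect_true(all(gap_null_probability(L, N + 10, G) <= p + 1e-15))
  }
})

test_that("classification rule is total, pure and matches its definition", {
  expect_equal(classify_call(0.37, 0.00), "E")
  expect_equal(classify_call(0.00, 0.90), "NE")
  expect_equal(classify_call(0.00, 0.00), "F")
  expect_equal(classify_call(0.50, 0.20), "F")
  expect_error(classify_call(1.2, 0), "\\[0, 1\\]")
  # every two-decimal grid point gets exactly one category
  grid <- expand.grid(pe = seq(0, 1, by = 0.05), pne = seq(0, 1, by = 0.05))
  cats <- classify_call(grid$pe, grid$pne)
  expect_true(all(cats %in% c("E", "NE", "F")))
  expect_equal(cats, classify_call(grid$pe, grid$pne))
})

test_that("two-decimal rounding is round-half-up at the boundary", {
  r2 <- tnseqr:::round2_frac
  expect_equal(r2(1, 200), 0.01)        # exactly 0.005
  expect_equal(r2(4999, 1000000), 0.00) # 0.004999
  expect_equal(r2(15, 1000), 0.02)      # 0.015 rounds up, not to even
  expect_equal(r2(0, 7), 0)
  expect_equal(r2(7, 7), 1)
})

test_that("worked toy regions score as hand-computed and match the oracle", {
  G <- 10000L
  sites <- toy_sites_10k()
  tab <- table_from_positions(sites, G = G)
  model <- scoring_model(G = G, N = 500L, alpha = 0.01, w = 10L)
  # significant gap length at these parameters is 92 bp
  expect_true(gap_null_probability(92, 500, G) <= 0.01)
  expect_false(gap_null_probability(91, 500, G) <= 0.01)

  r1 <- score_region(c(2051L, 2550L), tab, model)  # inside a 600 bp gap
  expect_equal(r1$P_E, 1.00)
  expect_equal(r1$P_NE, 0.00)
  expect_equal(r1$category, "E")

  r2 <- score_region(c(4001L, 4200L), tab, model)  # sites every 20 bp
  expect_equal(r2$P_E, 0.00)
  expect_equal(r2$P_NE, 1.00)
  expect_equal(r2$category, "NE")

  r3 <- score_region(c(6001L, 6060L), tab, model)  # 88 bp gap, sites 15 bp away
  expect_equal(r3$P_E, 0.00)
  expect_equal(r3$P_NE, 0.00)
  expect_equal(r3$category, "F")

  for (reg in list(c(2051L, 2550L), c(4001L, 4200L), c(6001L, 6060L))) {
    got <- score_region(reg, tab, model)
    want <- oracle_score(reg[1], reg[2], sites, G, 500L, 0.01, 10L)
    expect_equal(got$P_E, want$P_E)
    expect_equal(got$P_NE, want$P_NE)
  }
  expect_error(score_region(c(1, 10), table_from_positions(integer(), G = G),
                            model), "N = 0")
})

test_that("scores are invariant under genome rotation and strand reflection", {
  set.seed(11)
  G <- 5000L
  pos <- sort(sample.int(G, 120))
  model <- scoring_model(G = G, N = 120L, alpha = 0.01, w = 21L)
  tab <- table_from_positions(pos, G = G)
  reg <- c(1200L, 1900L)
  base <- score_region(reg, tab, model)
  for (delta in c(137L, 2500L, 4999L)) {
    rot <- ((pos - 1L + delta) %% G) + 1L
    reg_rot <- ((reg - 1L + delta) %% G) + 1L
    if (reg_rot[1] <= reg_rot[2]) {   # skip rotations that wrap the region
      got <- score_region(reg_rot, table_from_positions(rot, G = G), model)
      expect_equal(got$P_E, base$P_E)
      expect_equal(got$P_NE, base$P_NE)
    }
  }
  refl <- sort(G - pos + 1L)
  reg_refl <- sort(G - reg + 1L)
  got <- score_region(reg_refl, table_from_positions(refl, G = G), model)
  expect_equal(got$P_E, base$P_E)
  expect_equal(got$P_NE, base$P_NE)
})

test_that("threshold calibration reproduces exhaustive-search worked examples", {
  ann <- data.frame(id = c("gE1", "gE2", "gE3", "gN1", "gN2", "gN3"),
                    type = "ORF",
                    start = c(101, 301, 501, 701, 901, 1101),
                    end = c(200, 400, 600, 800, 1000, 1200),
                    strand = "+", stringsAsFactors = FALSE)
  gold <- gold_set(c("gE1", "gE2", "gE3"), c("gN1", "gN2", "gN3"))
  mk <- function(pos, reads) table_from_positions(pos, reads = reads, G = 1300L)

  tab1 <- mk(c(110, 120, 130, 710, 720), c(1, 2, 3, 100, 150))
  c1 <- calibrate_read_threshold(tab1, gold, ann)
  expect_equal(c1$relaxed, 4L)
  expect_equal(c1$stringent, 100L)
  # exhaustive-search oracle over the full curve
  err <- vapply(c1$error_curve$threshold, function(t)
    sum(c(1, 2, 3) >= t) + sum(c(100, 150) < t), numeric(1))
  expect_equal(c1$error_curve$error, err)

  tab2 <- mk(c(110, 120, 130, 710, 720, 730), c(1, 2, 10, 5, 20, 30))
  c2 <- calibrate_read_threshold(tab2, gold, ann)
  expect_equal(c2$relaxed, 3L)
  expect_equal(c2$stringent, 20L)
  expect_equal(min(c2$error_curve$error), 1)

  # identical distributions in both classes: degenerate, warned
  tab3 <- mk(c(110, 120, 710, 720), c(5, 9, 5, 9))
  expect_warning(c3 <- calibrate_read_threshold(tab3, gold, ann), "inseparable")
  expect_equal(c3$relaxed, c3$stringent)
  expect_true(c3$degenerate)

  # a gold class without insertions is an error
  tab4 <- mk(c(710, 720), c(5, 9))
  expect_error(calibrate_read_threshold(tab4, gold, ann), "calibration undefined")
})

test_that("timepoint selection follows the gold-set decay rule", {
  n <- 20L
  ann <- data.frame(
    id = c(sprintf("e%02d", 1:n), sprintf("n%02d", 1:n)), type = "ORF",
    start = c(1000 * (1:n), 50000 + 1000 * (1:n)),
    end = c(1000 * (1:n) + 99, 50000 + 1000 * (1:n) + 99),
    strand = "+", stringsAsFactors = FALSE)
  gold <- gold_set(sprintf("e%02d", 1:n), sprintf("n%02d", 1:n))
  e_sites <- function(k) {  # k insertions spread over the E genes
    g <- rep(1:n, length.out = k)
    1000 * g + seq_len(k) %% 90
  }
  ne_sites <- function(per_gene)
    as.vector(outer(seq_len(per_gene) * 4, 50000 + 1000 * (1:n), `+`))
  mk <- function(e_k, ne_per, day)
    table_from_positions(c(e_sites(e_k), ne_sites(ne_per)), G = 100000L, day = day)
  tabs <- list(`4` = mk(100, 20, 4), `8` = mk(20, 19, 8), `12` = mk(1, 19, 12))
  sel <- select_timepoint(tabs, gold, ann)
  expect_equal(sel$day, 12)
  expect_equal(sel$diagnostics$e_mean, c(5, 1, 0.05))
  expect_equal(sel$diagnostics$ne_mean, c(20, 19, 19))

  # bottleneck: non-essential insertions collapse too
  tabs_bad <- list(`4` = mk(100, 20, 4), `8` = mk(20, 19, 8), `12` = mk(1, 2, 12))
  expect_error(select_timepoint(tabs_bad, gold, ann), "bottleneck")

  # single qualifying day returns it with a warning
  expect_warning(sel1 <- select_timepoint(tabs["12"], gold, ann), "single")
  expect_equal(sel1$day, 12)
})

test_that("insertion counts in a dispensable region follow the Poisson rate", {
  # pooled over seeds, the count in a 10 kb non-essential span at 0.05/bp
  # stays inside the central Poisson band and is not rejected by a GOF test
  counts <- integer(10)
  for (s in seq_len(10)) {
    cfg <- sim_config(seed = 100 + s, genome_length = 30000L, n_orfs = 2L,
                      n_smorfs = 0L, n_ncrnas = 0L, n_convrnas = 0L,
                      frac_essential = 0, frac_fitness = 0,
                      n_essential_intergenic = 0L,
                      insertion_rate_ne = 0.05, noise_rate_e = 0,
                      reads_ne_mean = 50, reads_e_mean = 1, passage_days = 0)
    sim <- simulate_genome(cfg)
    tab <- simulate_insertions(sim)[[1]]
    counts[s] <- sum(tab$position >= 10001 & tab$position <= 20000)
  }
  # reads>=1 filter removes the NB zero class; expected per-seed rate
  p0 <- dnbinom(0, size = 1 / 0.5, mu = 50)
  lambda <- 10000 * 0.05 * (1 - p0)
  pooled <- sum(counts)
  expect_gt(ppois(pooled, 10 * lambda), 5e-4)
  expect_lt(ppois(pooled, 10 * lambda), 1 - 5e-4)
})
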