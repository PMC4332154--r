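test_that("clr matrix is symmetric, non-negative and flags duplicates", {
  set.seed(16)
  x <- matrix(rnorm(25 * 10), nrow = 25,
              dimnames = list(paste0("f", 1:25), NULL))
  x <- rbind(x, dup = x["f1", ])   # exact duplicate among independent noise
  res <- clr_matrix(x)
  expect_true(all(res$clr >= 0))
  expect_equal(res$clr, t(res$clr))
  expect_equal(res$mi, t(res$mi))
  # the duplicated pair attains the maximum CLR score in the matrix
  expect_equal(max(res$clr), res$clr["f1", "dup"])
  # permutation equivariance
  perm <- sample(nrow(x))
  res_p <- clr_matrix(x[perm, ])
  expect_equal(res_p$clr[rownames(x), rownames(x)], res$clr)
  # errors on degenerate input shapes
  expect_error(clr_matrix(x[, 1:2]), "3 timepoints")
  expect_error(clr_matrix(x[1:2, ]), "3 features")
})

test_that("gaussian mutual information is zero iff r is zero, monotone in |r|", {
  r <- seq(-0.99, 0.99, by = 0.01)
  mi <- -0.5 * log(1 - r^2)
  expect_true(all(mi >= 0))
  expect_equal(mi[r == 0], 0)
  o <- order(abs(r))
  expect_true(all(diff(mi[o]) >= -1e-12))
})

test_that("constant features warn and score zero information", {
  set.seed(17)
  x <- matrix(rnorm(10 * 8), nrow = 10,
              dimnames = list(paste0("f", 1:10), NULL))
  x[3, ] <- 5
  expect_warning(res <- clr_matrix(x), "zero-variance")
  expect_true(all(res$mi[3, ] == 0))
  expect_true(all(is.finite(res$clr)))
})

test_that("pair classification applies the threshold and sign rules", {
  clr <- structure(list(
    clr = matrix(c(0, 4, 1, 3, 4, 0, 0, 0, 1, 0, 0, 0, 3, 0, 0, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4])),
    r = matrix(c(0, -0.8, -0.9, 0, -0.8, 0, 0, 0, -0.9, 0, 0, 0, 0, 0, 0, 0),
               4, 4, dimnames = list(letters[1:4], letters[1:4])),
    mi = matrix(0, 4, 4), features = letters[1:4]), class = "clr_result")
  pairs <- data.frame(ncrna = c("a", "a", "a"), orf = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  out <- classify_pairs(clr, pairs, threshold = 2.5)
  expect_equal(out$sign, c("anti-correlated", NA, "undetermined"))
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
  expect_error(classify_pairs(clr, data.frame(ncrna = "a", orf = "zz")),
               "absent")
})

test_that("welch test matches the reference implementation and conventions", {
  g1 <- c(60, 55, 65, 70)
  g2 <- c(30, 35, 40, 45)
  w <- welch_test(g1, g2)
  ref <- t.test(g1, g2, var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p.value, ref$p.value)
  # hand computation via the Welch formulas
  se <- sqrt(var(g1) / 4 + var(g2) / 4)
  t_hand <- (mean(g1) - mean(g2)) / se
  df_hand <- se^4 / ((var(g1) / 4)^2 / 3 + (var(g2) / 4)^2 / 3)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p.value, 2 * pt(-abs(t_hand), df_hand))
  # degenerate zero-variance conventions
  z <- welch_test(c(50, 50, 50), c(50, 50, 50))
  expect_equal(z$t, 0)
  expect_equal(z$p.value, 1)
  expect_error(welch_test(1, c(2, 3)), "n >= 2")
})

test_that("essentiality enrichment aggregates per-ncRNA percentages", {
  sp <- data.frame(
    ncrna = c("n1", "n1", "n2", "n2", "n3", "n4", "n5", "n6"),
    orf = paste0("o", 1:8),
    sign = c("anti-correlated", "anti-correlated", "anti-correlated",
             "anti-correlated", "anti-correlated", "correlated",
             "correlated", "correlated"),
    stringsAsFactors = FALSE)
  calls <- data.frame(id = paste0("o", 1:8),
                      category = c("E", "E", "E", "NE", "E", "NE", "NE", "E"),
                      stringsAsFactors = FALSE)
  enr <- essentiality_enrichment(sp, calls)
  per <- enr$per_ncrna
  expect_equal(per$pct_essential[per$ncrna == "n1"], 100)
  expect_equal(per$pct_essential[per$ncrna == "n2"], 50)
  expect_equal(enr$welch$n, c(3L, 3L))
  expect_equal(enr$welch$means[1], mean(c(100, 50, 100)))
  expect_equal(enr$welch$means[2], mean(c(0, 0, 100)))
})

test_that("planted anti-correlated enrichment is detected with power", {
  # anti-correlated partners strongly enriched for essential ORFs
  detected <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 300 + s, genome_length = 60000L, n_orfs = 36L,
                      n_ncrnas = 24L, frac_essential = 0.5,
                      frac_anticorrelated = 0.25, anticorr_e_weight = 3.8,
                      expression_noise_sd = 0.3)
    sim <- simulate_genome(cfg)
    expr <- simulate_expression(sim)
    truth_pairs <- attr(expr, "pairs")
    clr <- clr_matrix(expr)
    sp <- classify_pairs(clr, truth_pairs[, c("ncrna", "orf")], 2.5)
    calls <- data.frame(id = sim$annotation$id,
                        category = sim$annotation$truth)
    enr <- tryCatch(essentiality_enrichment(sp, calls), error = function(e) NULL)
    if (!is.null(enr) && enr$welch$p.value < 0.01) detected <- detected + 1L
  }
  expect_gte(detected / n_seeds, 0.85)
})
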