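test_that("Fisher exact 2x2 matches enumeration and stated conventions", {
  ft <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(ft$log2_odds_ratio, 0)
  expect_equal(ft$p, 1)

  tab <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  ft2 <- fisher_exact_2x2(tab)
  expect_equal(ft2$log2_odds_ratio, 4)
  expect_equal(ft2$p, fisher_p_enum(tab), tolerance = 1e-12)

  # Haldane-Anscombe correction with a zero cell
  ft3 <- fisher_exact_2x2(matrix(c(3, 0, 1, 4), 2, byrow = TRUE))
  expect_equal(ft3$log2_odds_ratio, log2((3.5 * 4.5) / (0.5 * 1.5)))
  expect_equal(ft3$log2_odds_ratio, log2(21))

  # zero margin: flagged, p = 1
  ft4 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_false(ft4$testable)
  expect_equal(ft4$p, 1)
  expect_true(is.na(ft4$log2_odds_ratio))
})

test_that("Fisher p equals hypergeometric enumeration for all small tables", {
  for (a in 0:6) for (b in 0:6) for (c_ in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (sum(tab) > 18) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_p_enum(tab),
                 tolerance = 1e-9,
                 info = paste(a, b, c_, d))
  }
})

test_that("Fisher symmetries: double swap invariance, single swap flips sign", {
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    ft <- fisher_exact_2x2(tab)
    both <- fisher_exact_2x2(tab[2:1, 2:1])
    expect_equal(both$p, ft$p, tolerance = 1e-12)
    expect_equal(both$log2_odds_ratio, ft$log2_odds_ratio,
                 tolerance = 1e-12)
    flip <- fisher_exact_2x2(tab[2:1, ])
    expect_equal(flip$log2_odds_ratio, -ft$log2_odds_ratio,
                 tolerance = 1e-12)
  }
})

test_that("partial Spearman reduces to plain Spearman and handles ties", {
  set.seed(42)
  x <- rnorm(60)
  y <- exp(x)  # monotone transform
  expect_equal(partial_spearman(x, y)$rho, 1)

  y2 <- rnorm(60)
  plain <- cor(x, y2, method = "spearman")
  expect_equal(partial_spearman(x, y2)$rho, plain, tolerance = 1e-12)

  # constant confounder contributes nothing
  withc <- partial_spearman(x, y2, confounders = cbind(const = rep(1, 60)))
  expect_equal(withc$rho, plain, tolerance = 1e-12)

  # tied data still matches the average-rank Spearman
  xt <- sample(1:5, 60, replace = TRUE)
  yt <- sample(1:4, 60, replace = TRUE)
  expect_equal(partial_spearman(xt, yt)$rho,
               cor(xt, yt, method = "spearman"), tolerance = 1e-12)

  expect_warning(res <- partial_spearman(rep(1, 10), rnorm(10)),
                 "constant")
  expect_true(is.na(res$rho))
  expect_error(partial_spearman(1:3, 1:3, confounders = cbind(1:3, 3:1)),
               "too few")
})

test_that("adjusting for the planted common cause removes the correlation", {
  set.seed(43)
  z <- rnorm(2000)
  x <- z + rnorm(2000)
  y <- z + rnorm(2000)
  unadj <- partial_spearman(x, y)
  adj <- partial_spearman(x, y, confounders = cbind(z = z))
  expect_gt(unadj$rho, 0.3)
  expect_lt(abs(adj$rho), 0.08)
  expect_gt(adj$p, 1e-4)
})

test_that("BH adjustment follows the step-up formula within families", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  p <- c(0.01, 0.02, 0.03, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, fam), c(0.02, 0.02, 0.04, 0.04))

  # output is monotone in the input order statistics
  set.seed(47)
  for (i in 1:10) {
    p2 <- runif(15)
    q2 <- bh_adjust(p2)
    expect_identical(order(q2[order(p2)]), seq_len(15))
    expect_true(all(q2 <= 1))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("association screen ranks a self-target first and respects order", {
  set.seed(44)
  coll <- generate_genome_collection(cohort_spec(n_genomes = 60, seed = 45))
  com <- generate_communities(cohort_spec(n_genomes = 60, n_samples = 80,
                                          seed = 45), coll$truth)
  freq <- auxotrophy_frequency(com$abundance, coll$truth)
  targets <- data.frame(self = freq[, "trp"],
                        noise = rnorm(nrow(freq)),
                        row.names = rownames(freq))
  res <- association_screen(freq, targets)
  self_trp <- res[res$amino_acid == "trp" & res$target == "self", ]
  expect_equal(self_trp$estimate, 1)
  expect_equal(self_trp$p_adjusted, min(res$p_adjusted))

  # row order of inputs does not change results
  perm <- sample(nrow(freq))
  res2 <- association_screen(freq[perm, ], targets[perm, , drop = FALSE])
  expect_equal(res2, res, tolerance = 1e-12)
})

test_that("fully permuted targets keep the FDR at its nominal level", {
  set.seed(46)
  n <- 80
  freq <- matrix(runif(n * 20), n, 20,
                 dimnames = list(sprintf("s%03d", 1:n),
                                 amino_acids()$amino_acid))
  frac <- replicate(100, {
    targets <- data.frame(t1 = rnorm(n), t2 = rnorm(n),
                          row.names = rownames(freq))
    res <- association_screen(freq, targets)
    mean(res$p_adjusted < 0.05)
  })
  expect_lte(mean(frac), 0.05)
})
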