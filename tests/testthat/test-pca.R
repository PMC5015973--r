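# Independent oracle: eigendecomposition of the gene-gene covariance
# matrix of the centered sample x gene data.
eigen_pca_oracle <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- xc %*% ev$vectors
  list(scores = scores, lambda = ev$values,
       percent = 100 * ev$values / sum(ev$values))
}

pca_design <- function(samples, sexes) {
  data.frame(sample_id = samples, sex = sexes, genotype = "control_het",
             stage = "E13.5",
             replicate = as.integer(stats::ave(seq_along(samples), sexes,
                                               FUN = seq_along)),
             stringsAsFactors = FALSE)
}

test_that("a rank-1 two-group contrast loads entirely on PC1", {
  expr <- rbind(inf = c(1, 1, 1, -1, -1, -1),
                flat1 = rep(5, 6), flat2 = rep(2, 6))
  colnames(expr) <- sprintf("s%d", 1:6)
  d <- pca_design(colnames(expr), rep(c("male", "female"), each = 3))
  p <- run_subset_pca(expr, d, rownames(expr), c("male", "control_het"))
  expect_equal(p$percent_var[1], 100, tolerance = 1e-9)
  expect_equal(abs(p$loadings["inf", 1]), 1, tolerance = 1e-9)
  expect_equal(unname(p$loadings[c("flat1", "flat2"), 1]), c(0, 0))
  # orientation: male group mean positive, and the gene tracks it
  expect_gt(mean(p$scores[1:3, 1]), 0)
  expect_equal(p$loadings["inf", 1], 1, tolerance = 1e-9)
})

test_that("scores and variances match the covariance eigendecomposition", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(4:10, 1); g <- sample(3:10, 1)
    expr <- matrix(rnorm(n * g, mean = 8), nrow = g,
                   dimnames = list(sprintf("g%d", 1:g),
                                   sprintf("s%d", 1:n)))
    d <- pca_design(colnames(expr),
                    rep(c("male", "female"), length.out = n))
    p <- run_subset_pca(expr, d, rownames(expr), c("male", "control_het"))
    o <- eigen_pca_oracle(t(expr))
    k <- min(n - 1, g)
    for (j in seq_len(k)) {
      # equal up to sign
      err <- min(max(abs(p$scores[, j] - o$scores[, j])),
                 max(abs(p$scores[, j] + o$scores[, j])))
      expect_lt(err, 1e-8)
    }
    expect_equal(p$percent_var, o$percent[seq_len(k)] *
                   sum(o$percent[seq_len(k)]) ^ -1 * 100,
                 tolerance = 1e-8)
    expect_equal(sum(p$percent_var), 100, tolerance = 1e-6)
    expect_true(all(p$percent_var >= -1e-12))
    expect_true(all(abs(p$loadings) <= 1 + 1e-9))
    expect_equal(ncol(p$scores), k)
  }
})

test_that("flipping the orientation group negates PC1 only", {
  sim <- simulate_gonad_expression(tiny_config())
  germ <- gene_set(truth_gene_sets(sim$truth),
                   c("male_germ", "female_germ"))
  a <- run_subset_pca(sim$expr, sim$design, germ, c("male", "control_het"))
  b <- run_subset_pca(sim$expr, sim$design, germ, c("female", "control_het"))
  expect_equal(a$scores[, 1], -b$scores[, 1], tolerance = 1e-12)
  expect_equal(a$loadings[, 1], -b$loadings[, 1], tolerance = 1e-12)
  expect_equal(a$percent_var, b$percent_var, tolerance = 1e-12)
})

test_that("degenerate PCA inputs are rejected", {
  expr <- rbind(g1 = rep(3, 4), g2 = rep(1, 4))
  colnames(expr) <- sprintf("s%d", 1:4)
  d <- pca_design(colnames(expr), rep(c("male", "female"), each = 2))
  expect_error(run_subset_pca(expr, d, rownames(expr),
                              c("male", "control_het")), "zero variance")
  expr2 <- expr; expr2[1, 1] <- 4
  expect_error(run_subset_pca(expr2, d, c("g1", "gX"),
                              c("male", "control_het")), "gX")
  expect_error(run_subset_pca(expr2[, 1:2], d[1:2, ], rownames(expr2),
                              c("male", "control_het")), "3 samples")
  expect_error(run_subset_pca(expr2, d, character(),
                              c("male", "control_het")), "non-empty")
})

test_that("exchangeable loading groups give a null contribution test", {
  l <- c(stats::setNames(seq(0.1, 0.9, length.out = 10),
                         sprintf("g%d", 1:10)),
         stats::setNames(seq(0.1, 0.9, length.out = 10),
                         sprintf("s%d", 1:10)))
  sets <- gene_set_table(names(l), rep(c("male_germ", "male_soma"),
                                       each = 10))
  ct <- contribution_test(make_pca_loadings(l), sets)
  expect_gte(ct$p_value, 0.99)
  expect_equal(ct$median_abs_germ, ct$median_abs_soma)
})

test_that("fully separated loading groups give a vanishing p-value", {
  set.seed(33)
  l <- c(stats::setNames(0.9 + runif(50, -0.02, 0.02),
                         sprintf("g%d", 1:50)),
         stats::setNames(0.1 + runif(50, -0.02, 0.02),
                         sprintf("s%d", 1:50)))
  sets <- gene_set_table(names(l),
                         rep(c("female_germ", "female_soma"), each = 50))
  ct <- contribution_test(make_pca_loadings(l), sets)
  expect_lt(ct$p_value, 1e-7)
  expect_gt(ct$median_abs_germ, ct$median_abs_soma)
})

test_that("the rank-sum p-value matches exact permutation enumeration", {
  set.seed(5)
  g <- 0.85 + runif(6, -0.05, 0.05)
  s <- 0.15 + runif(6, -0.05, 0.05)
  l <- stats::setNames(c(g, s), sprintf("x%d", 1:12))
  sets <- gene_set_table(names(l), rep(c("male_germ", "male_soma"),
                                       each = 6))
  ct <- contribution_test(make_pca_loadings(l), sets)

  # enumerate all 6-of-12 assignments of the pooled values to "germ"
  pool <- c(g, s)
  obs <- sum(rank(pool)[1:6])
  perms <- utils::combn(12, 6)
  stats_all <- apply(perms, 2, function(idx) sum(rank(pool)[idx]))
  p_exact <- 2 * min(mean(stats_all <= obs), mean(stats_all >= obs))
  expect_equal(ct$p_value, min(1, p_exact), tolerance = 1e-12)

  expect_error(contribution_test(make_pca_loadings(l[c(1, 7)]),
                                 gene_set_table(names(l)[c(1, 7)],
                                                c("male_germ",
                                                  "male_soma"))),
               "at least 2")
})

test_that("germ-subset PCA separates simulated sexes along PC1", {
  sim <- simulate_gonad_expression(sim_config(seed = 17L))
  sets <- derive_gene_sets(sim$expr, sim$design)
  germ <- gene_set(sets, c("male_germ", "female_germ"))
  p <- run_subset_pca(sim$expr, sim$design, germ, c("male", "control_het"),
                      groups = list(c("male", "control_het"),
                                    c("female", "control_het"),
                                    c("female", "smad4_ko"),
                                    c("female", "dko")))
  m_testis <- pc1_group_mean(p, sim$design, c("male", "control_het"))
  m_ovary <- pc1_group_mean(p, sim$design, c("female", "control_het"))
  m_smad4 <- pc1_group_mean(p, sim$design, c("female", "smad4_ko"))
  m_dko <- pc1_group_mean(p, sim$design, c("female", "dko"))
  expect_gt(m_testis, m_ovary)
  # DKO sits between the control sexes, past the single KO toward male
  expect_gt(m_dko, m_ovary)
  expect_lt(m_dko, m_testis)
  expect_gt(m_dko, m_smad4)
})
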