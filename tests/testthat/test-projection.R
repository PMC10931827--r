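test_that("PCA biplot matches an independent eigendecomposition", {
  set.seed(41)
  m <- matrix(rlnorm(12 * 9, 2, 1), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:9)))
  bp <- pca_biplot(m)
  # eigen oracle on the gene correlation matrix
  X <- scale(t(m))
  eig <- eigen(stats::cor(t(m)))
  scores_oracle <- X %*% eig$vectors
  for (j in 1:2) {
    a <- bp$scores[, j]
    b <- scores_oracle[, j]
    expect_lt(min(sum(abs(a - b)), sum(abs(a + b))), 1e-8)
  }
  ve_oracle <- eig$values / sum(eig$values)
  expect_equal(unname(bp$var_explained),
               ve_oracle[seq_along(bp$var_explained)], tolerance = 1e-8)
  expect_true(all(diff(bp$var_explained) <= 1e-12))
  expect_equal(sum(bp$var_explained), 1)
})

test_that("two perfectly correlated genes give a rank-one projection", {
  s <- sprintf("s%d", 1:6)
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = 2 * c(1, 2, 3, 4, 5, 6))
  colnames(m) <- s
  bp <- pca_biplot(m)
  expect_equal(bp$var_explained[1], 1)
})

test_that("orientation rule removes the arbitrary SVD sign", {
  set.seed(43)
  base <- rlnorm(20, 3, 1)
  m <- outer(base, c(0.3, 0.5, 0.8, 1.2, 1.8, 2.5)) *
    matrix(rlnorm(120, 0, 0.1), nrow = 20)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6))
  bp <- pca_biplot(m)
  # convention: gene PC1 coordinates correlate non-negatively with mean FPKM
  expect_gte(stats::cor(bp$genes[, 1], rowMeans(m)), 0)
  # reordering rows (which can flip raw SVD signs) leaves the oriented
  # geometry identical up to row order
  perm <- sample(nrow(m))
  bp2 <- pca_biplot(m[perm, ])
  expect_equal(bp2$genes[rownames(m), 1], bp$genes[, 1], tolerance = 1e-8)
  expect_equal(abs(bp2$scores[, 1]), abs(bp$scores[, 1]), tolerance = 1e-8)
  expect_equal(bp2$scores[, 1], bp$scores[, 1], tolerance = 1e-8)
})

test_that("zero-variance genes are dropped and degenerate input errors", {
  m <- rbind(flat = rep(5, 4), g1 = c(1, 2, 3, 4), g2 = c(4, 1, 3, 2))
  colnames(m) <- sprintf("s%d", 1:4)
  expect_message(bp <- pca_biplot(m), "zero-variance")
  expect_identical(bp$dropped, "flat")
  expect_equal(nrow(bp$genes), 2L)
  allflat <- rbind(a = rep(1, 4), b = rep(2, 4))
  colnames(allflat) <- sprintf("s%d", 1:4)
  expect_error(suppressMessages(pca_biplot(allflat)), "zero variance")
})

test_that("side counts split items by axis sign with zeros flagged right", {
  set.seed(44)
  m <- matrix(rlnorm(30 * 8), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  bp <- pca_biplot(m)
  sc <- side_counts(bp, what = "genes")
  expect_equal(sc$n_left + sc$n_right, 30L)
  v <- bp$genes[, 1]
  expect_equal(sc$n_left, sum(v < 0))
  expect_error(side_counts(bp, items = c("nope")), "no matching")

  sub <- side_counts(bp, items = sprintf("g%02d", 1:5), what = "genes")
  expect_equal(sub$n, 5L)
})

test_that("elevated genes land on the high-expression side of PC1", {
  spec <- expression_sim_spec(n_genes = 200, n_region_specific = 0,
                              n_shared = 0, n_group_effect = 40,
                              group_fold = 4, cv = 0.2, seed = 6)
  sim <- simulate_expression(spec)
  hpt <- sim$metadata$sample_id[sim$metadata$region == "HPT"]
  bp <- pca_biplot(sim$expression, samples = hpt)
  planted <- sim$truth$gene[sim$truth$label == "group"]
  sc <- side_counts(bp, items = planted, what = "genes")
  expect_gte(sc$n_right / sc$n, 0.9)
})

test_that("exact binomial test equals brute-force enumeration for n <= 15", {
  for (n in c(5, 10, 15)) {
    # enumerate all 2^n equally likely outcomes once
    tails <- vapply(0:n, function(s) choose(n, s), numeric(1)) / 2^n
    for (k in 0:n) {
      ge <- sum(tails[(k + 1):(n + 1)])
      le <- sum(tails[1:(k + 1)])
      two <- sum(tails[tails <= tails[k + 1] * (1 + 1e-07)])
      expect_equal(binomial_side_test(n, k, "greater")$p_value, ge)
      expect_equal(binomial_side_test(n, k, "less")$p_value, le)
      expect_equal(binomial_side_test(n, k)$p_value, min(1, two))
      # independent cross-check against stats::binom.test
      expect_equal(binomial_side_test(n, k)$p_value,
                   stats::binom.test(k, n)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("binomial side test reproduces published tail probabilities", {
  expect_equal(signif(binomial_side_test(18, 18, "greater")$p_value, 2),
               3.8e-06)
  p_hpt <- binomial_side_test(46, 9)$p_value
  expect_lte(p_hpt, 0.00045)
  expect_equal(p_hpt, 4.06e-05, tolerance = 0.01)
  expect_equal(binomial_side_test(2, 1)$p_value, 1)
  # symmetry at p0 = 0.5
  for (n in c(7, 12, 46)) {
    for (k in 0:3) {
      expect_equal(binomial_side_test(n, k)$p_value,
                   binomial_side_test(n, n - k)$p_value)
    }
  }
})

test_that("side preference reports both sidedness conventions", {
  set.seed(45)
  m <- matrix(rlnorm(40 * 6), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  bp <- pca_biplot(m)
  sp <- side_preference(bp, what = "genes")
  expect_identical(colnames(sp),
                   c("what", "axis", "n", "n_left", "n_right", "n_zero",
                     "p_two_sided", "p_right_ge"))
  expect_equal(sp$p_two_sided,
               binomial_side_test(sp$n, sp$n_right)$p_value)
})

test_that("agglomerative clustering recovers structure deterministically", {
  s <- sprintf("s%d", 1:6)
  m <- rbind(a1 = c(1, 2, 3, 4, 5, 6), a2 = c(1, 2, 3, 4, 5, 6),
             b1 = c(6, 5, 4, 3, 2, 1))
  colnames(m) <- s
  cl <- ahc_cluster(m, k = 2)
  # identical profiles merge first, at height zero
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(cl$assignment[["a1"]], cl$assignment[["a2"]])
  expect_false(cl$assignment[["a1"]] == cl$assignment[["b1"]])

  # two well-separated blobs recovered exactly at k = 2
  set.seed(46)
  blob1 <- matrix(rnorm(10 * 8, 0), nrow = 10)
  blob2 <- matrix(rnorm(10 * 8, 0), nrow = 10)
  blob2[, 1:4] <- blob2[, 1:4] + 10
  mm <- rbind(blob1, blob2)
  dimnames(mm) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8))
  cl2 <- ahc_cluster(mm, k = 2, standardize = FALSE)
  expect_equal(length(unique(cl2$assignment[1:10])), 1L)
  expect_equal(length(unique(cl2$assignment[11:20])), 1L)
  expect_false(cl2$assignment[[1]] == cl2$assignment[[20]])

  # permuting input order changes no memberships (up to relabelling)
  perm <- sample(20)
  cl3 <- ahc_cluster(mm[perm, ], k = 2, standardize = FALSE)
  tab <- table(cl2$assignment[rownames(mm)[perm]], cl3$assignment)
  expect_equal(sum(tab > 0), 2L)

  expect_error(ahc_cluster(mm, k = 2, linkage = "centroid"), "arg")
  expect_error(ahc_cluster(mm[1, , drop = FALSE], k = 1), "at least 2")
})
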