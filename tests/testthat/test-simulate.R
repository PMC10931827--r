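test_that("simulator is deterministic under a fixed seed", {
  spec <- expression_sim_spec(n_genes = 100, n_region_specific = 5,
                              n_shared = 5, n_group_effect = 5, seed = 42)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a, b)
  c_ <- simulate_expression(expression_sim_spec(n_genes = 100,
    n_region_specific = 5, n_shared = 5, n_group_effect = 5, seed = 43))
  expect_false(identical(a$expression, c_$expression))

  ps <- ppi_sim_spec(seed = 9)
  genes <- sprintf("g%03d", 1:50)
  g1 <- simulate_ppi(ps, genes)
  g2 <- simulate_ppi(ps, genes)
  expect_identical(igraph::as_data_frame(g1$graph),
                   igraph::as_data_frame(g2$graph))
})

test_that("noise-free generation gives closed-form region means and TSI", {
  # no planted signal, no noise: every region mean equal, TSI = 1/5
  spec <- expression_sim_spec(n_genes = 50, n_region_specific = 0,
                              n_shared = 0, n_group_effect = 0,
                              region_fold = 1, cv = 0, seed = 1)
  sim <- simulate_expression(spec)
  rm_ <- region_means(sim$expression, sim$metadata)
  expect_true(all(abs(rm_ - rm_[, 1]) < 1e-12))
  tsi <- apply(rm_, 1, function(x) tsi_single(x)$tsi)
  expect_equal(unname(tsi), rep(0.2, 50))

  # one planted gene at fold 10, no noise: means (b,b,b,b,10b), TSI 10/14
  spec2 <- expression_sim_spec(n_genes = 10, regions = brain_regions(),
                               n_region_specific = 1, n_shared = 0,
                               n_group_effect = 0, region_fold = 10,
                               cv = 0, seed = 2)
  sim2 <- simulate_expression(spec2)
  planted <- sim2$truth$gene[startsWith(sim2$truth$label, "region:")]
  rm2 <- region_means(sim2$expression, sim2$metadata)
  g <- planted[1]
  tgt <- sub("region:", "", sim2$truth$label[sim2$truth$gene == g])
  others <- setdiff(brain_regions(), tgt)
  expect_equal(rm2[g, tgt], 10 * rm2[g, others[1]])
  expect_equal(tsi_single(rm2[g, ])$tsi, 10 / 14)
})

test_that("planted signals survive multiplicative noise on average", {
  spec <- expression_sim_spec(n_genes = 600, n_region_specific = 20,
                              n_shared = 0, n_group_effect = 0,
                              region_fold = 10, cv = 0.2, seed = 1)
  sim <- simulate_expression(spec)
  rm_ <- region_means(sim$expression, sim$metadata)
  planted <- sim$truth$gene[startsWith(sim$truth$label, "region:")]
  expect_length(planted, 100L)
  tsi <- vapply(planted, function(g) tsi_single(rm_[g, ])$tsi, numeric(1))
  expect_lt(abs(mean(tsi) - 10 / 14), 0.05)
})

test_that("group-effect genes are elevated in affected groups only", {
  spec <- expression_sim_spec(n_genes = 50, n_region_specific = 0,
                              n_shared = 0, n_group_effect = 5,
                              group_fold = 3, cv = 0, seed = 4,
                              group_regions = "HPT")
  sim <- simulate_expression(spec)
  g <- sim$truth$gene[sim$truth$label == "group"][1]
  meta <- sim$metadata
  hpt_ctrl <- meta$sample_id[meta$region == "HPT" & meta$group == "control"]
  hpt_aggr <- meta$sample_id[meta$region == "HPT" &
                               meta$group == "aggressive"]
  hpc_aggr <- meta$sample_id[meta$region == "HPC" &
                               meta$group == "aggressive"]
  expect_equal(mean(sim$expression[g, hpt_aggr]),
               3 * mean(sim$expression[g, hpt_ctrl]))
  # masked out of HPC: no elevation there
  expect_equal(mean(sim$expression[g, hpc_aggr]),
               mean(sim$expression[g, hpt_ctrl]))
})

test_that("simulator spec validation rejects impossible designs", {
  expect_error(expression_sim_spec(n_genes = 10, n_region_specific = 5),
               "exceed")
  expect_error(expression_sim_spec(region_fold = 0.5), ">= 1")
  expect_error(expression_sim_spec(cv = -1), "cv")
  expect_error(expression_sim_spec(shared_pair = c("MRN", "MRN")),
               "distinct")
  expect_error(ppi_sim_spec(background_p = 1.5), "probabilities")
  expect_error(ppi_sim_spec(tier_cutoffs = c(0.4, 0.2)), "increasing")
})

test_that("synthetic graphs realise the requested edge model", {
  genes <- sprintf("g%03d", 1:30)
  mod <- genes[1:10]
  # background 0, module 1: exactly the 45 module edges, all above the
  # lowest tier cutoff
  pp <- simulate_ppi(ppi_sim_spec(background_p = 0, within_p = 1, seed = 1),
                     genes, modules = list(mod))
  expect_equal(igraph::ecount(pp$graph), 45L)
  expect_equal(igraph::ecount(tier_subgraph(pp$graph, mod, 0.15)), 45L)
  expect_true(all(igraph::E(pp$graph)$score > 0.15 &
                    igraph::E(pp$graph)$score < 1))

  # within prob == background prob: observed/expected ratio near 1
  pp0 <- simulate_ppi(ppi_sim_spec(background_p = 0.2, within_p = 0.2,
                                   seed = 2), genes, modules = list(mod))
  en <- permutation_enrichment(pp0$graph, mod, cutoff = 0.15, B = 499,
                               seed = 3)
  expect_gt(en$p_value, 0.05)

  # mean module edge count ~ within_p * C(set, 2) across seeds
  genes50 <- sprintf("g%03d", 1:60)
  mod50 <- genes50[1:50]
  counts <- vapply(1:30, function(s) {
    g <- simulate_ppi(ppi_sim_spec(background_p = 0.02, within_p = 0.3,
                                   seed = s), genes50,
                      modules = list(mod50))$graph
    igraph::ecount(tier_subgraph(g, mod50, 0))
  }, numeric(1))
  expected <- 0.3 * choose(50, 2)
  expect_lt(abs(mean(counts) - expected) / expected, 0.05)

  expect_error(simulate_ppi(ppi_sim_spec(), genes,
                            modules = list(c("nope"))), "not in universe")
})

test_that("a simulated bundle round-trips through the IO layer", {
  sim <- simulate_expression(expression_sim_spec(n_genes = 40,
    n_region_specific = 2, n_shared = 2, n_group_effect = 2, seed = 8))
  dir <- withr::local_tempdir()
  ppi <- simulate_ppi(ppi_sim_spec(seed = 8), rownames(sim$expression))
  write_sim_bundle(sim, dir, ppi = ppi)
  expect_true(all(file.exists(file.path(dir, c("expression.tsv",
                                               "metadata.tsv", "truth.tsv",
                                               "ppi.tsv")))))
  m <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(m, sim$expression, tolerance = 1e-12)
  md <- read_metadata_tsv(file.path(dir, "metadata.tsv"))
  expect_identical(md, sim$metadata)
  g <- read_string_links(file.path(dir, "ppi.tsv"))
  expect_equal(igraph::ecount(g), igraph::ecount(ppi$graph))
  canon <- function(gr) {
    d <- igraph::as_data_frame(gr)
    d$key <- paste(pmin(d$from, d$to), pmax(d$from, d$to))
    d <- d[order(d$key), c("key", "score")]
    rownames(d) <- NULL
    d
  }
  expect_equal(canon(g), canon(ppi$graph), tolerance = 1e-10)
})
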