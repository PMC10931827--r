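# Synthetic FPKM data and scored interaction graphs with planted ground
# truth. The generator emulates the study design the package targets: five
# brain regions x three groups x three replicates, log-normal baseline FPKM,
# planted single-region and shared-pair specific genes at a configurable
# fold elevation, planted group-effect genes, multiplicative log-normal
# noise. Identical spec + seed gives identical output.

#' Specification for a synthetic expression data set
#'
#' Collects and validates the parameters of [simulate_expression()].
#' Defaults reproduce the study design the package targets: 5 regions x
#' 3 groups x 3 replicates, a 10-fold regional elevation of planted specific
#' genes and multiplicative noise with coefficient of variation 0.3.
#'
#' @param n_genes Total number of genes.
#' @param regions Region labels.
#' @param groups Group labels.
#' @param replicates Samples per region x group cell.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline FPKM (log scale).
#' @param n_region_specific Planted single-region-specific genes per region.
#' @param shared_pair Region pair for planted shared-pair genes.
#' @param n_shared Planted genes elevated in both members of `shared_pair`.
#' @param region_fold Fold elevation `f >= 1` of planted genes in their
#'   target region(s).
#' @param n_group_effect Planted group-effect genes.
#' @param group_fold Fold elevation `g >= 1` of group-effect genes in the
#'   affected groups.
#' @param affected_groups Groups carrying the planted group effect.
#' @param group_regions Optional region mask restricting the group effect
#'   (default `NULL`: all regions), so e.g. a hypothalamic hormone elevation
#'   confined to affected groups can be emulated.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   noise; `0` gives exact expected values.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Validated list of class `"expression_sim_spec"`.
#' @export
expression_sim_spec <- function(n_genes = 2000,
                                regions = brain_regions(),
                                groups = stress_groups(),
                                replicates = 3,
                                baseline_meanlog = 2,
                                baseline_sdlog = 1.5,
                                n_region_specific = 20,
                                shared_pair = c("MRN", "VTA"),
                                n_shared = 10,
                                region_fold = 10,
                                n_group_effect = 20,
                                group_fold = 3,
                                affected_groups = c("aggressive",
                                                    "depressive"),
                                group_regions = NULL,
                                cv = 0.3,
                                seed = 1) {
  spec <- list(n_genes = n_genes, regions = regions, groups = groups,
               replicates = replicates, baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog,
               n_region_specific = n_region_specific,
               shared_pair = shared_pair, n_shared = n_shared,
               region_fold = region_fold, n_group_effect = n_group_effect,
               group_fold = group_fold, affected_groups = affected_groups,
               group_regions = group_regions, cv = cv, seed = seed)
  if (n_genes < 1 || n_region_specific < 0 || n_shared < 0 ||
      n_group_effect < 0 || replicates < 1)
    stop("counts must be non-negative (n_genes, replicates >= 1)")
  if (region_fold < 1 || group_fold < 1) stop("fold factors must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  if (!is.null(shared_pair)) {
    if (length(shared_pair) != 2L || !all(shared_pair %in% regions) ||
        shared_pair[1L] == shared_pair[2L])
      stop("shared_pair must be two distinct declared regions")
  } else if (n_shared > 0) {
    stop("n_shared > 0 requires a shared_pair")
  }
  if (!all(affected_groups %in% groups))
    stop("affected_groups must be declared group labels")
  if (!is.null(group_regions) && !all(group_regions %in% regions))
    stop("group_regions must be declared region labels")
  n_planted <- n_region_specific * length(regions) + n_shared +
    n_group_effect
  if (n_planted > n_genes)
    stop("planted gene counts (", n_planted, ") exceed n_genes (", n_genes,
         ")")
  structure(spec, class = "expression_sim_spec")
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' Draws a log-normal baseline FPKM per gene and multiplies in (i) the
#' regional fold for planted single-region and shared-pair genes, (ii) the
#' group fold for planted group-effect genes in affected groups (optionally
#' restricted to a region mask), and (iii) multiplicative log-normal noise
#' with unit mean and the requested coefficient of variation. With `cv = 0`
#' every sample equals its expectation, so for a planted single-region gene
#' at fold `f` across `n` regions the TSI is exactly `f / (f + n - 1)`.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `expression` (genes x samples matrix), `metadata`
#'   (sample_id/region/group data frame) and `truth` (per-gene `label` in
#'   `{background, region:<R>, shared, group}` plus `target`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  regions <- spec$regions
  genes <- sprintf("g%04d", seq_len(n))
  meta <- expand.grid(rep = seq_len(spec$replicates), group = spec$groups,
                      region = regions, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%d", meta$region, meta$group, meta$rep),
    region = meta$region, group = meta$group, stringsAsFactors = FALSE)

  # planted gene bookkeeping: consecutive blocks, provably disjoint
  label <- rep("background", n)
  target <- rep(NA_character_, n)
  idx <- 0L
  for (r in regions) {
    if (spec$n_region_specific > 0) {
      pick <- idx + seq_len(spec$n_region_specific)
      label[pick] <- paste0("region:", r)
      target[pick] <- r
      idx <- idx + spec$n_region_specific
    }
  }
  if (spec$n_shared > 0) {
    pick <- idx + seq_len(spec$n_shared)
    label[pick] <- "shared"
    target[pick] <- paste(spec$shared_pair, collapse = "/")
    idx <- idx + spec$n_shared
  }
  if (spec$n_group_effect > 0) {
    pick <- idx + seq_len(spec$n_group_effect)
    label[pick] <- "group"
    target[pick] <- paste(spec$affected_groups, collapse = "/")
  }

  baseline <- stats::rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  expect <- matrix(baseline, nrow = n, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (i in which(startsWith(label, "region:"))) {
    expect[i, meta$region == target[i]] <-
      expect[i, meta$region == target[i]] * spec$region_fold
  }
  for (i in which(label == "shared")) {
    in_pair <- meta$region %in% spec$shared_pair
    expect[i, in_pair] <- expect[i, in_pair] * spec$region_fold
  }
  grp_cols <- meta$group %in% spec$affected_groups &
    (is.null(spec$group_regions) | meta$region %in%
       (spec$group_regions %||% regions))
  for (i in which(label == "group")) {
    expect[i, grp_cols] <- expect[i, grp_cols] * spec$group_fold
  }

  if (spec$cv > 0) {
    s <- sqrt(log(1 + spec$cv^2))
    noise <- matrix(stats::rlnorm(length(expect), -s^2 / 2, s),
                    nrow = n)  # unit-mean multiplicative noise
    values <- expect * noise
  } else {
    values <- expect
  }
  truth <- data.frame(gene = genes, label = label, target = target,
                      stringsAsFactors = FALSE)
  list(expression = values, metadata = meta, truth = truth)
}

#' Specification for a synthetic scored interaction graph
#'
#' Parameters of [simulate_ppi()]: an Erdős–Rényi background with
#' planted high-connectivity modules and per-edge confidence scores drawn
#' uniformly within the four standard confidence-tier bands so that tier
#' filtering is always exercised.
#'
#' @param background_p Edge probability between node pairs not inside a
#'   common module.
#' @param within_p Edge probability inside a planted module (replaces, not
#'   supplements, the background probability there).
#' @param tier_cutoffs Strictly increasing score cutoffs in (0, 1) bounding
#'   the bands edges are drawn from; default `c(0.15, 0.4, 0.7, 0.9)`.
#' @param seed Integer seed.
#' @return Validated list of class `"ppi_sim_spec"`.
#' @export
ppi_sim_spec <- function(background_p = 0.02, within_p = 0.3,
                         tier_cutoffs = c(0.15, 0.4, 0.7, 0.9), seed = 1) {
  if (background_p < 0 || background_p > 1 || within_p < 0 || within_p > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (any(tier_cutoffs <= 0) || any(tier_cutoffs >= 1) ||
      is.unsorted(tier_cutoffs, strictly = TRUE))
    stop("tier_cutoffs must be strictly increasing within (0, 1)")
  structure(list(background_p = background_p, within_p = within_p,
                 tier_cutoffs = tier_cutoffs, seed = seed),
            class = "ppi_sim_spec")
}

#' Generate a scored random interaction graph with planted modules
#'
#' Every unordered node pair receives an edge independently, with probability
#' `within_p` when both nodes share a planted module and `background_p`
#' otherwise. Each realised edge gets a confidence tier drawn uniformly from
#' the four bands defined by `tier_cutoffs` and a score uniform within its
#' band, so all tiers are populated in expectation.
#'
#' @param spec A [ppi_sim_spec()].
#' @param genes Character vector: the node universe.
#' @param modules Optional (named) list of gene sets to plant as
#'   high-connectivity modules; unknown genes are a hard error.
#' @return List with `graph` (an undirected [igraph::igraph] with edge
#'   attribute `score` in (0, 1) and all of `genes` as vertices) and `truth`
#'   (per-edge data frame flagging within-module edges).
#' @export
simulate_ppi <- function(spec, genes, modules = list()) {
  stopifnot(inherits(spec, "ppi_sim_spec"))
  if (anyDuplicated(genes)) stop("duplicate gene ids in node universe")
  for (m in modules) {
    unknown <- setdiff(m, genes)
    if (length(unknown) > 0L)
      stop("module gene(s) not in universe: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  set.seed(spec$seed)
  n <- length(genes)
  pr <- t(utils::combn(n, 2L))
  within <- rep(FALSE, nrow(pr))
  for (m in modules) {
    im <- which(genes %in% m)
    within <- within | (pr[, 1L] %in% im & pr[, 2L] %in% im)
  }
  p <- ifelse(within, spec$within_p, spec$background_p)
  keep <- stats::runif(nrow(pr)) < p
  edges <- pr[keep, , drop = FALSE]
  within <- within[keep]
  bands <- c(spec$tier_cutoffs, 1)
  tier <- sample.int(length(spec$tier_cutoffs), nrow(edges), replace = TRUE)
  score <- stats::runif(nrow(edges), min = bands[tier], max = bands[tier + 1L])
  el <- data.frame(protein1 = genes[edges[, 1L]],
                   protein2 = genes[edges[, 2L]],
                   score = score, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = genes)
  truth <- data.frame(protein1 = el$protein1, protein2 = el$protein2,
                      within_module = within, stringsAsFactors = FALSE)
  list(graph = g, truth = truth)
}

#' Write a simulated data bundle to disk
#'
#' Serialises the outputs of [simulate_expression()] (and optionally
#' [simulate_ppi()]) as the plain-text files the pipeline reads back:
#' `expression.tsv`, `metadata.tsv`, `truth.tsv` and, when a graph is given,
#' `ppi.tsv` in the scored-links dialect (0-1 scores).
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @param ppi Optional result of [simulate_ppi()].
#' @return Invisibly, the vector of file paths written.
#' @export
write_sim_bundle <- function(sim, dir, ppi = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_expression_tsv(sim$expression, file.path(dir, "expression.tsv")),
    write_table(sim$metadata, file.path(dir, "metadata.tsv")),
    write_table(sim$truth, file.path(dir, "truth.tsv")))
  if (!is.null(ppi)) {
    el <- igraph::as_data_frame(ppi$graph, what = "edges")
    names(el) <- c("protein1", "protein2", "combined_score")
    paths <- c(paths, write_table(el, file.path(dir, "ppi.tsv")))
  }
  invisible(paths)
}
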