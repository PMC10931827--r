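# Config-driven end-to-end orchestration: validate a YAML run configuration,
# execute alignment -> region means -> BRSG selection -> breakdown ->
# (optional) network enrichment -> per-region biplots, side tests, AHC ->
# panel profiles, and write every table plus a checksum manifest. One seed
# governs all stochastic stages; sub-seeds are derived deterministically.

run_config_defaults <- function() {
  list(expression = NULL, metadata = NULL, ppi = NULL, panels = NULL,
       regions = brain_regions(), groups = stress_groups(),
       pair = c("MRN", "VTA"), tau = 0.5, tier_thresholds = c(100, 1000),
       score_cutoffs = as.list(tier_cutoffs()), permutations = 999,
       seed = 1, pca_scale = TRUE, ahc_clusters = 2, outdir = "brsg_out")
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a plain list, fills in defaults (threshold
#' 0.5, expression tiers 100/1000 FPKM, confidence cutoffs
#' 0.150/0.4/0.7/0.9, 999 permutations), rejects unknown keys, and
#' aggregates all validation failures into a single readable error.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list of class `"brsg_config"`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errors <- character()
  if (length(unknown) > 0L)
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  if (is.null(cfg$expression))
    errors <- c(errors, "missing required key: expression")
  if (is.null(cfg$metadata))
    errors <- c(errors, "missing required key: metadata")
  if (!(is.numeric(cfg$tau) && length(cfg$tau) == 1L && cfg$tau > 0 &&
        cfg$tau < 1))
    errors <- c(errors, "tau must be a single number in (0, 1)")
  tt <- unlist(cfg$tier_thresholds)
  if (any(tt <= 0) || is.unsorted(tt, strictly = TRUE))
    errors <- c(errors, "tier_thresholds must be increasing and positive")
  sc <- unlist(cfg$score_cutoffs)
  if (any(sc <= 0) || any(sc >= 1) || is.unsorted(sc, strictly = TRUE))
    errors <- c(errors,
                "score_cutoffs must be strictly increasing within (0, 1)")
  if (!(is.numeric(cfg$permutations) && cfg$permutations >= 99))
    errors <- c(errors, "permutations must be at least 99")
  if (!is.null(cfg$pair) &&
      (length(cfg$pair) != 2L || !all(cfg$pair %in% cfg$regions)))
    errors <- c(errors, "pair must name two declared regions")
  if (length(errors) > 0L)
    stop("invalid run configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  cfg$tier_thresholds <- tt
  cfg$score_cutoffs <- sc
  structure(cfg, class = "brsg_config")
}

#' Run the full BRSG pipeline
#'
#' Executes every stage the configuration enables and writes all result
#' tables under `outdir`: `brsg_table.tsv`, `breakdown.tsv`, optionally
#' `enrichment.tsv`, per-region `biplot_scores.tsv` / `biplot_loadings.tsv`
#' / `side_tests.tsv` / `clusters.tsv`, panel outputs, and `manifest.tsv`
#' recording the package version, seed, and an MD5 checksum per file. A
#' stage failure aborts with the stage name and removes partial outputs.
#' Reruns with the same inputs and seed produce identical checksums.
#'
#' @param config Path to a YAML config, a list, or a `"brsg_config"`.
#' @return Invisibly, a run report: the fit, output paths and the manifest.
#' @export
run_brsg_pipeline <- function(config) {
  if (!inherits(config, "brsg_config")) config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  report <- tryCatch({
    set.seed(config$seed)
    sub_seeds <- sample.int(.Machine$integer.max, 4L)

    stage <- "read_inputs"
    expr <- read_expression_tsv(config$expression)
    meta <- read_metadata_tsv(config$metadata, regions = config$regions,
                              groups = config$groups)

    stage <- "select_brsgs"
    fit <- brsg(expr, meta, pair = config$pair, tau = config$tau,
                tiers = config$tier_thresholds, regions = config$regions)
    p <- file.path(config$outdir, "brsg_table.tsv")
    write_brsg_table(fit, p); written <- c(written, p)
    p <- file.path(config$outdir, "breakdown.tsv")
    write_table(breakdown(fit), p); written <- c(written, p)

    sets <- brsg_gene_sets(fit)
    al <- align_samples(expr, meta)

    if (!is.null(config$ppi)) {
      stage <- "network_enrichment"
      graph <- read_string_links(config$ppi)
      cutoffs <- setNames(config$score_cutoffs,
                          names(tier_cutoffs())[seq_along(
                            config$score_cutoffs)])
      rep_df <- enrichment_report(graph, sets, cutoffs = cutoffs,
                                  B = config$permutations,
                                  seed = sub_seeds[1L])
      p <- file.path(config$outdir, "enrichment.tsv")
      write_table(rep_df, p); written <- c(written, p)
    }

    stage <- "projection"
    scores_l <- list(); loads_l <- list(); sides_l <- list()
    clust_l <- list()
    for (nm in names(sets)) {
      reg <- strsplit(nm, "/", fixed = TRUE)[[1L]]
      samp <- al$metadata$sample_id[al$metadata$region %in% reg]
      genes <- sets[[nm]]
      if (length(genes) < 2L || length(samp) < 2L) {
        message("projection: skipping set '", nm,
                "' (needs >= 2 genes and samples)")
        next
      }
      bp <- tryCatch(pca_biplot(al$expression, genes = genes,
                                samples = samp, scale = config$pca_scale),
                     error = function(e) NULL)
      if (is.null(bp)) {
        message("projection: skipping set '", nm, "' (degenerate)")
        next
      }
      scores_l[[nm]] <- data.frame(set = nm,
                                   sample_id = rownames(bp$scores),
                                   pc1 = bp$scores[, 1L],
                                   pc2 = bp$scores[, 2L],
                                   stringsAsFactors = FALSE)
      loads_l[[nm]] <- data.frame(set = nm, gene = rownames(bp$genes),
                                  pc1 = bp$genes[, 1L],
                                  pc2 = bp$genes[, 2L],
                                  stringsAsFactors = FALSE)
      sides_l[[nm]] <- cbind(set = nm,
                             side_preference(bp, what = "genes"))
      if (length(genes) >= 3L) {
        cl <- ahc_cluster(al$expression, genes = genes,
                          k = min(config$ahc_clusters, length(genes) - 1L))
        clust_l[[nm]] <- data.frame(set = nm,
                                    gene = names(cl$assignment),
                                    cluster = unname(cl$assignment),
                                    stringsAsFactors = FALSE)
      }
    }
    for (pair_ in list(list(scores_l, "biplot_scores.tsv",
                            c("set", "sample_id")),
                       list(loads_l, "biplot_loadings.tsv",
                            c("set", "gene")),
                       list(sides_l, "side_tests.tsv", "set"),
                       list(clust_l, "clusters.tsv", c("set", "gene")))) {
      if (length(pair_[[1L]]) > 0L) {
        p <- file.path(config$outdir, pair_[[2L]])
        write_table(do.call(rbind, pair_[[1L]]), p, sort_by = pair_[[3L]])
        written <- c(written, p)
      }
    }

    stage <- "panels"
    panels <- if (is.null(config$panels)) builtin_panels()
              else read_gene_panels(config$panels)
    prof_l <- list(); contr_l <- list()
    for (nm in names(panels)) {
      pp <- tryCatch(panel_profile(al$expression, al$metadata,
                                   panels[[nm]], name = nm),
                     error = function(e) NULL)
      if (is.null(pp)) {
        message("panels: skipping panel '", nm,
                "' (no genes in matrix)")
        next
      }
      prof_l[[nm]] <- cbind(panel = nm, pp$means)
      grps <- unique(al$metadata$group)
      base <- config$groups[1L]
      for (g in setdiff(grps, base)) {
        gc <- group_contrast(pp, g, base)
        contr_l[[paste(nm, g)]] <- cbind(panel = nm, contrast =
                                           paste0(g, "_vs_", base), gc)
      }
    }
    if (length(prof_l) > 0L) {
      p <- file.path(config$outdir, "panel_profile.tsv")
      write_table(do.call(rbind, prof_l), p,
                  sort_by = c("panel", "gene", "region", "group"))
      written <- c(written, p)
    }
    if (length(contr_l) > 0L) {
      p <- file.path(config$outdir, "group_contrast.tsv")
      write_table(do.call(rbind, contr_l), p,
                  sort_by = c("panel", "contrast", "gene", "region"))
      written <- c(written, p)
    }

    stage <- "manifest"
    manifest <- data.frame(
      file = basename(written),
      md5 = unname(tools::md5sum(written)),
      stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$file), , drop = FALSE]
    info <- data.frame(
      file = c(".version", ".seed"),
      md5 = c(as.character(utils::packageVersion("brsgkit")),
              as.character(config$seed)), stringsAsFactors = FALSE)
    p <- file.path(config$outdir, "manifest.tsv")
    write_table(rbind(info, manifest), p)
    written <- c(written, p)

    list(fit = fit, files = written, manifest = manifest,
         outdir = config$outdir)
  }, error = on_fail)
  invisible(report)
}
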