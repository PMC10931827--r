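# Tissue-specificity index (TSI) and BRSG selection.
#
# For a gene with mean FPKM x_i in each of n regions,
#   TSI_single   = max_i x_i / sum_i x_i
#   TSI_combined = (x_a + x_b) / sum_i x_i   for a designated region pair
# A gene is a brain-region-specific gene (BRSG) when its TSI strictly
# exceeds a soft threshold tau (default 0.5). The single-region rule takes
# precedence over the combined-pair rule.

#' Per-region mean expression profiles
#'
#' Arithmetic mean FPKM per gene over all samples of each region, pooling all
#' experimental groups. A declared region with no samples is a hard error.
#'
#' @param expression Genes-by-samples numeric matrix.
#' @param metadata Sample metadata aligned to the matrix (see
#'   [align_samples()]).
#' @param regions Region labels, in the order used for tie-breaking. Default:
#'   first appearance order in `metadata`.
#' @return Numeric matrix, genes x regions.
#' @export
region_means <- function(expression, metadata, regions = NULL) {
  miss <- setdiff(colnames(expression), metadata$sample_id)
  if (length(miss) > 0L)
    stop("samples missing from metadata (run align_samples first): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  regions <- regions %||% unique(metadata$region)
  out <- matrix(NA_real_, nrow = nrow(expression), ncol = length(regions),
                dimnames = list(rownames(expression), regions))
  for (r in regions) {
    s <- metadata$sample_id[metadata$region == r]
    s <- s[s %in% colnames(expression)]
    if (length(s) == 0L) stop("region '", r, "' has no samples")
    out[, r] <- rowMeans(expression[, s, drop = FALSE])
  }
  out
}

#' Single-region tissue-specificity index
#'
#' `tsi_single()` computes max/sum over a profile of per-region means and
#' identifies the argmax region; ties are broken by declared region order and
#' flagged. `tsi_combined()` sums a designated pair of regions in the
#' numerator instead, for genes shared between two similar regions.
#'
#' An all-zero profile has no defined TSI; `NA` is returned (callers skip and
#' log such genes).
#'
#' @param x Named non-negative numeric vector of per-region mean FPKM.
#' @return For `tsi_single()`, a list with `tsi`, `region` (argmax label) and
#'   `tie` (logical). For `tsi_combined()`, a single numeric value.
#' @examples
#' tsi_single(c(HPC = 0.29, HPT = 0.05, STR = 0.01, MRN = 3.89, VTA = 16.42))
#' tsi_combined(c(HPC = 0.3, HPT = 0.08, STR = 0.21, MRN = 11.8, VTA = 16.1),
#'              pair = c("MRN", "VTA"))
#' @export
tsi_single <- function(x) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (any(x < 0)) stop("region means must be non-negative")
  s <- sum(x)
  if (s <= 0) return(list(tsi = NA_real_, region = NA_character_, tie = FALSE))
  i <- which.max(x)  # first max = declared region order tie-break
  list(tsi = unname(x[i] / s), region = names(x)[i],
       tie = sum(x == x[i]) > 1L)
}

#' @rdname tsi_single
#' @param pair Character vector of two distinct region labels whose means are
#'   summed in the numerator.
#' @export
tsi_combined <- function(x, pair) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("pair must name two distinct regions")
  if (!all(pair %in% names(x)))
    stop("pair region(s) absent from profile: ",
         paste(setdiff(pair, names(x)), collapse = ", "))
  if (any(x < 0)) stop("region means must be non-negative")
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  unname((x[pair[1L]] + x[pair[2L]]) / s)
}

#' Select brain-region-specific genes
#'
#' Fits the tissue-specificity model: per-region mean profiles are computed
#' from the aligned expression matrix, every gene is scored by the
#' single-region TSI and (optionally) the combined-pair TSI, and genes whose
#' index strictly exceeds `tau` are selected. The single-region rule takes
#' precedence: a gene passing it is assigned to its argmax region even if the
#' combined value is larger; otherwise, if a pair is declared and the
#' combined TSI passes, the gene is assigned to the pair. All-zero genes are
#' skipped with a log message.
#'
#' @param expression Genes-by-samples FPKM matrix.
#' @param metadata Sample metadata (columns `sample_id`, `region`, `group`).
#'   Samples are aligned to the matrix automatically.
#' @param pair Optional character vector of two regions for the combined
#'   rule (default `c("MRN", "VTA")`); `NULL` disables it.
#' @param tau Selection threshold in (0, 1); strict inequality. Default 0.5.
#' @param tiers Increasing positive FPKM thresholds for the expression-tier
#'   breakdown (default `c(100, 1000)`).
#' @param min_max_fpkm Genes whose maximal region mean is below this floor
#'   are never selected (default 0, i.e. no floor).
#' @param regions Region label order (default: first appearance in
#'   `metadata`).
#' @return Object of class `"brsg"`: a list with `records` (selected genes:
#'   `gene`, `rule`, `region`, `tsi`, `x_max`, `tie`), `scores` (all scored
#'   genes), `region_means`, `dropped` (all-zero gene ids), and the call
#'   parameters. Methods: [print.brsg()], [summary.brsg()], [coef.brsg()],
#'   [plot.brsg()], [breakdown()].
#' @examples
#' sim <- simulate_expression(expression_sim_spec(n_genes = 200, seed = 1))
#' fit <- brsg(sim$expression, sim$metadata)
#' fit
#' breakdown(fit)
#' @export
brsg <- function(expression, metadata, pair = c("MRN", "VTA"), tau = 0.5,
                 tiers = c(100, 1000), min_max_fpkm = 0, regions = NULL) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0 && tau < 1))
    stop("tau must be a single number in (0, 1)")
  check_tiers(tiers)
  al <- align_samples(expression, metadata)
  rm_ <- region_means(al$expression, al$metadata, regions = regions)
  regions <- colnames(rm_)
  if (!is.null(pair)) {
    if (length(pair) != 2L || pair[1L] == pair[2L] ||
        !all(pair %in% regions))
      stop("pair must name two distinct declared regions")
  }
  tot <- rowSums(rm_)
  dropped <- rownames(rm_)[tot <= 0]
  if (length(dropped) > 0L)
    message("brsg: skipped ", length(dropped),
            " gene(s) with all-zero region means")
  keep <- tot > 0
  m <- rm_[keep, , drop = FALSE]
  tot <- tot[keep]
  amax <- max.col(m, ties.method = "first")
  x_max <- m[cbind(seq_len(nrow(m)), amax)]
  tsi_s <- x_max / tot
  tie <- rowSums(m == x_max) > 1L
  tsi_c <- if (!is.null(pair)) (m[, pair[1L]] + m[, pair[2L]]) / tot
           else rep(NA_real_, nrow(m))
  scores <- data.frame(gene = rownames(m),
                       tsi_single = unname(tsi_s),
                       region = regions[amax],
                       tie = unname(tie),
                       tsi_combined = unname(tsi_c),
                       x_max = unname(x_max),
                       stringsAsFactors = FALSE)
  eligible <- apply(m, 1L, max) >= min_max_fpkm
  sel_single <- eligible & tsi_s > tau
  sel_comb <- eligible & !sel_single & !is.na(tsi_c) & tsi_c > tau
  rec_s <- scores[sel_single, c("gene", "region", "tsi_single", "x_max",
                                "tie")]
  rec_s$rule <- rep("single", nrow(rec_s))
  names(rec_s)[names(rec_s) == "tsi_single"] <- "tsi"
  n_c <- sum(sel_comb)
  rec_c <- data.frame(gene = scores$gene[sel_comb],
                      region = rep(paste(pair, collapse = "/"), n_c),
                      tsi = scores$tsi_combined[sel_comb],
                      x_max = if (n_c > 0)
                        m[sel_comb, pair[1L]] + m[sel_comb, pair[2L]]
                      else numeric(),
                      tie = rep(FALSE, n_c),
                      rule = rep("combined", n_c),
                      stringsAsFactors = FALSE)
  records <- rbind(rec_s[, c("gene", "rule", "region", "tsi", "x_max", "tie")],
                   rec_c[, c("gene", "rule", "region", "tsi", "x_max", "tie")])
  records <- records[order(-records$tsi, records$gene), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, scores = scores, region_means = rm_,
                 dropped = dropped, regions = regions, pair = pair,
                 tau = tau, tiers = tiers, min_max_fpkm = min_max_fpkm,
                 n_genes = nrow(expression), n_samples = ncol(al$expression),
                 call = match.call()),
            class = "brsg")
}

check_tiers <- function(tiers) {
  if (length(tiers) == 0L || any(tiers <= 0) || is.unsorted(tiers,
                                                            strictly = TRUE))
    stop("tiers must be strictly increasing positive FPKM thresholds")
  invisible(tiers)
}

#' Expression-tier breakdown of a BRSG selection
#'
#' For each region, counts selected genes assigned to it (combined-pair genes
#' count in both member regions) and, per threshold, those whose mean FPKM in
#' that region strictly exceeds the threshold.
#'
#' @param object A `"brsg"` fit.
#' @param thresholds Strictly increasing positive FPKM thresholds; defaults
#'   to the fit's `tiers`.
#' @return Data frame with one row per region: `region`, `n_brsg`, and one
#'   `gt_<threshold>` count column per threshold.
#' @export
breakdown <- function(object, thresholds = object$tiers) {
  stopifnot(inherits(object, "brsg"))
  check_tiers(thresholds)
  rm_ <- object$region_means
  rec <- object$records
  rows <- lapply(object$regions, function(r) {
    in_pair <- if (nrow(rec) > 0L)
      vapply(strsplit(rec$region, "/", fixed = TRUE),
             function(p) r %in% p, logical(1L)) else logical(0L)
    member <- rec$region == r | (rec$rule == "combined" & in_pair)
    genes <- rec$gene[member]
    cnts <- vapply(thresholds, function(t) sum(rm_[genes, r] > t),
                   integer(1L))
    out <- data.frame(region = r, n_brsg = length(genes),
                      stringsAsFactors = FALSE)
    out[paste0("gt_", thresholds)] <- as.list(cnts)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @export
print.brsg <- function(x, ...) {
  cat("Brain-region-specific gene selection (TSI > ", x$tau, ")\n", sep = "")
  cat("  ", x$n_genes, " genes x ", x$n_samples, " samples, regions: ",
      paste(x$regions, collapse = ", "), "\n", sep = "")
  if (!is.null(x$pair))
    cat("  combined-pair rule: ", paste(x$pair, collapse = "/"), "\n",
        sep = "")
  tab <- table(factor(x$records$rule, levels = c("single", "combined")))
  cat("  selected: ", nrow(x$records), " gene(s) (",
      tab[["single"]], " single, ", tab[["combined"]], " combined)\n",
      sep = "")
  if (length(x$dropped) > 0L)
    cat("  skipped ", length(x$dropped), " all-zero gene(s)\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname print.brsg
#' @param object,x A `"brsg"` fit.
#' @param ... Unused.
summary.brsg <- function(object, ...) {
  structure(list(fit = object, breakdown = breakdown(object),
                 top = utils::head(object$records, 10L)),
            class = "summary.brsg")
}

#' @export
print.summary.brsg <- function(x, ...) {
  print(x$fit)
  cat("\nExpression-tier breakdown:\n")
  print(x$breakdown, row.names = FALSE)
  cat("\nTop genes by TSI:\n")
  df <- x$top
  df$tsi <- round(df$tsi, 2)  # outputs report 2 dp; full precision internal
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname print.brsg
coef.brsg <- function(object, ...) {
  setNames(object$records$tsi, object$records$gene)
}

#' @export
#' @rdname print.brsg
#' @param y Unused.
plot.brsg <- function(x, y, ...) {
  bd <- breakdown(x)
  graphics::barplot(setNames(bd$n_brsg, bd$region),
                    ylab = "selected genes", xlab = "region",
                    main = sprintf("BRSGs at TSI > %.2g", x$tau), ...)
  invisible(x)
}

#' Genes selected per region, as named gene sets
#'
#' Splits a `"brsg"` fit into one character vector of gene symbols per
#' assigned region (the combined pair forms its own set, named e.g.
#' `"MRN/VTA"`), the shape consumed by [enrichment_report()].
#'
#' @param object A `"brsg"` fit.
#' @return Named list of character vectors.
#' @export
brsg_gene_sets <- function(object) {
  stopifnot(inherits(object, "brsg"))
  split(object$records$gene, object$records$region)
}

#' Write the BRSG table to TSV
#'
#' One row per selected gene with the rule used, assigned region(s), TSI
#' (rounded to 2 decimals in the output; full precision is kept in the
#' object), per-region mean FPKM, and expression-tier flags. The tier flag of
#' a combined-pair gene uses the larger of the two member-region means.
#'
#' @param object A `"brsg"` fit.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_brsg_table <- function(object, path) {
  stopifnot(inherits(object, "brsg"))
  rec <- object$records
  df <- data.frame(gene = rec$gene, rule = rec$rule, region = rec$region,
                   tsi = round(rec$tsi, 2), stringsAsFactors = FALSE)
  means <- object$region_means[rec$gene, , drop = FALSE]
  colnames(means) <- paste0(colnames(means), "_avg")
  df <- cbind(df, as.data.frame(means, stringsAsFactors = FALSE))
  for (t in object$tiers) {
    flag <- vapply(seq_len(nrow(rec)), function(i) {
      if (rec$rule[i] == "combined") {
        max(object$region_means[rec$gene[i], object$pair]) > t
      } else {
        object$region_means[rec$gene[i], rec$region[i]] > t
      }
    }, logical(1L))
    df[[paste0("gt_", t)]] <- flag
  }
  rownames(df) <- NULL
  write_table(df, path, sort_by = "gene")
}

#' Bundled reference region-mean profiles for VTA/MRN marker genes
#'
#' A small reference table of per-region mean FPKM profiles for 24 mouse
#' genes specific to the ventral tegmental area and/or midbrain raphe nuclei
#' (dopaminergic/serotonergic midbrain), with their published
#' tissue-specificity indices (2 decimals) and segment membership (`VTA`,
#' `MRN`, or `shared` for the combined pair). Used as a desk-checkable worked
#' example: recomputing TSI from the printed means reproduces the published
#' column.
#'
#' @return Data frame with columns `gene`, `segment`, `HPC`, `HPT`, `STR`,
#'   `MRN`, `VTA`, `tsi_published`.
#' @examples
#' ref <- vta_mrn_reference()
#' row <- ref[ref$gene == "Dbh", ]
#' tsi_single(unlist(row[, c("HPC", "HPT", "STR", "MRN", "VTA")]))
#' @export
vta_mrn_reference <- function() {
  path <- system.file("extdata", "vta_mrn_marker_means.tsv",
                      package = "brsgkit", mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' @importFrom graphics barplot
NULL
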