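# Gene panel profiling: built-in marker panels, prefix-built panels (e.g.
# ribosomal subunit families), per-sample profiles with region x group
# means, and group contrasts.

#' Built-in gene panels
#'
#' Marker panels shipped with the package as an editable TSV
#' (`inst/extdata/panels.tsv`): vesicular glutamate/GABA transporters,
#' glycinergic transport with the neurofilament master gene, the
#' neurofilament triplet, striatal phosphodiesterases, five major TCA-cycle
#' enzymes, a partial mitophagy panel (only the named members; the full set
#' is not enumerated in public lists, so the file is meant to be extended),
#' and a myelin seed panel (Mbp; extend with your own membership).
#'
#' @return Named list of character vectors.
#' @examples
#' lengths(builtin_panels())
#' @export
builtin_panels <- function() {
  path <- system.file("extdata", "panels.tsv", package = "brsgkit",
                      mustWork = TRUE)
  read_gene_panels(path)
}

#' Build a gene panel from symbol prefixes
#'
#' Selects all genes in `gene_universe` whose symbol starts with any of the
#' given prefixes. Matching is anchored at the symbol start and
#' case-sensitive, so `"Rpl"` never matches `"Mrpl11"`. The result is sorted
#' and duplicate-free, hence order-independent and idempotent.
#'
#' @param gene_universe Character vector of gene symbols.
#' @param prefixes Non-empty character vector of prefixes.
#' @return Sorted character vector (possibly empty, with a warning).
#' @examples
#' prefix_panel(c("Rps5", "Rpl3", "Mrpl11", "Actb"), c("Rps", "Rpl"))
#' @export
prefix_panel <- function(gene_universe, prefixes) {
  if (length(prefixes) == 0L) stop("prefixes must be non-empty")
  hit <- Reduce(`|`, lapply(prefixes, function(p)
    startsWith(gene_universe, p)))
  panel <- sort(unique(gene_universe[hit]))
  if (length(panel) == 0L)
    warning("no genes match prefix(es): ", paste(prefixes, collapse = ", "))
  panel
}

#' Profile a gene panel across samples, regions and groups
#'
#' Long-format per-sample FPKM values for the panel genes plus region x
#' group mean FPKM. Panel genes absent from the matrix are reported (message
#' and `missing` element), never silently dropped; a panel with no genes
#' present is a hard error.
#'
#' @param expression Genes-by-samples FPKM matrix.
#' @param metadata Sample metadata (aligned automatically).
#' @param panel Character vector of gene symbols.
#' @param name Panel name carried into the output.
#' @return Object of class `"panel_profile"`: `name`, `values` (gene,
#'   sample, region, group, fpkm), `means` (gene, region, group, mean_fpkm),
#'   `missing`.
#' @export
panel_profile <- function(expression, metadata, panel, name = "panel") {
  al <- align_samples(expression, metadata)
  present <- intersect(panel, rownames(al$expression))
  missing <- setdiff(panel, present)
  if (length(present) == 0L)
    stop("no panel gene present in the expression matrix")
  if (length(missing) > 0L)
    message("panel_profile: ", length(missing),
            " panel gene(s) absent from matrix: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  sub <- al$expression[present, , drop = FALSE]
  values <- data.frame(
    gene = rep(present, times = ncol(sub)),
    sample_id = rep(colnames(sub), each = length(present)),
    fpkm = as.vector(sub), stringsAsFactors = FALSE)
  values$region <- al$metadata$region[match(values$sample_id,
                                            al$metadata$sample_id)]
  values$group <- al$metadata$group[match(values$sample_id,
                                          al$metadata$sample_id)]
  values <- values[, c("gene", "sample_id", "region", "group", "fpkm")]
  means <- stats::aggregate(fpkm ~ gene + region + group, data = values,
                            FUN = mean)
  names(means)[names(means) == "fpkm"] <- "mean_fpkm"
  means <- means[order(means$gene, means$region, means$group), ,
                 drop = FALSE]
  rownames(means) <- NULL
  structure(list(name = name, values = values, means = means,
                 missing = missing),
            class = "panel_profile")
}

#' @export
print.panel_profile <- function(x, ...) {
  cat("Panel '", x$name, "': ", length(unique(x$values$gene)),
      " gene(s) x ", length(unique(x$values$sample_id)), " samples",
      if (length(x$missing) > 0L)
        paste0(" (", length(x$missing), " panel gene(s) missing)"),
      "\n", sep = "")
  invisible(x)
}

#' Group contrast of a panel profile
#'
#' Per gene and region, the ratio and difference of mean FPKM between two
#' groups. Ratios with a zero denominator are flagged (`denom_zero`) and
#' reported as `NA` rather than infinity.
#'
#' @param profile A [panel_profile()] result.
#' @param group_a,group_b Group labels (numerator / denominator); unknown
#'   labels are a hard error.
#' @return Data frame: `gene`, `region`, `mean_a`, `mean_b`, `ratio`,
#'   `difference`, `denom_zero`.
#' @export
group_contrast <- function(profile, group_a, group_b) {
  stopifnot(inherits(profile, "panel_profile"))
  m <- profile$means
  known <- unique(m$group)
  bad <- setdiff(c(group_a, group_b), known)
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  a <- m[m$group == group_a, c("gene", "region", "mean_fpkm")]
  b <- m[m$group == group_b, c("gene", "region", "mean_fpkm")]
  merged <- merge(a, b, by = c("gene", "region"),
                  suffixes = c("_a", "_b"))
  out <- data.frame(gene = merged$gene, region = merged$region,
                    mean_a = merged$mean_fpkm_a,
                    mean_b = merged$mean_fpkm_b,
                    ratio = ifelse(merged$mean_fpkm_b > 0,
                                   merged$mean_fpkm_a / merged$mean_fpkm_b,
                                   NA_real_),
                    difference = merged$mean_fpkm_a - merged$mean_fpkm_b,
                    denom_zero = merged$mean_fpkm_b == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
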