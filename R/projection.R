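# PCA biplots of samples against gene sets, principal-axis side counts with
# exact binomial side-preference tests, and agglomerative hierarchical
# clustering of gene profiles.

#' PCA biplot of samples against a gene set
#'
#' Genes are standardised (centred, unit variance) across the chosen samples
#' (correlation-mode PCA, so mixed-magnitude FPKM ranges do not let a few
#' highly expressed genes dominate; set `scale = FALSE` for covariance
#' mode). Components come from the SVD of the samples-by-genes matrix.
#' Sample scores and gene coordinates (loadings scaled by the component
#' standard deviations) share the same axes. Because the sign of an SVD axis
#' is arbitrary, PC1 is oriented so that gene PC1 coordinates correlate
#' non-negatively with gene mean expression, i.e. "right = elevated overall
#' expression"; PC2's sign is fixed by making its largest-magnitude gene
#' coordinate positive. Zero-variance genes are dropped with a message.
#'
#' @param expression Genes-by-samples FPKM matrix.
#' @param genes,samples Optional subsets (default: all).
#' @param scale Standardise genes to unit variance (default `TRUE`).
#' @return Object of class `"brsg_biplot"`: `scores` (samples x PCs),
#'   `genes` (gene coordinates), `var_explained`, `orientation` (sign flips
#'   applied per axis), `dropped` (zero-variance gene ids).
#' @export
pca_biplot <- function(expression, genes = NULL, samples = NULL,
                       scale = TRUE) {
  genes <- genes %||% rownames(expression)
  samples <- samples %||% colnames(expression)
  genes <- intersect(genes, rownames(expression))
  samples <- intersect(samples, colnames(expression))
  sub <- expression[genes, samples, drop = FALSE]
  if (ncol(sub) < 2L) stop("need at least 2 samples")
  sds <- apply(sub, 1L, stats::sd)
  dropped <- rownames(sub)[sds == 0]
  if (length(dropped) > 0L) {
    message("pca_biplot: dropped ", length(dropped),
            " zero-variance gene(s)")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (nrow(sub) == 0L) stop("all genes have zero variance")
  if (nrow(sub) < 2L) stop("need at least 2 genes with variance")
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = scale)
  gene_coords <- sweep(pc$rotation, 2L, pc$sdev, `*`)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  flips <- rep(1, ncol(pc$x))
  gm <- rowMeans(sub)
  if (stats::sd(gene_coords[, 1L]) > 0 && stats::sd(gm) > 0 &&
      stats::cor(gene_coords[, 1L], gm) < 0)
    flips[1L] <- -1
  if (ncol(gene_coords) >= 2L) {
    lead <- which.max(abs(gene_coords[, 2L]))
    if (gene_coords[lead, 2L] < 0) flips[2L] <- -1
  }
  scores <- sweep(pc$x, 2L, flips, `*`)
  gene_coords <- sweep(gene_coords, 2L, flips, `*`)
  structure(list(scores = scores, genes = gene_coords,
                 var_explained = var_explained, orientation = flips,
                 scaled = scale, dropped = dropped),
            class = "brsg_biplot")
}

#' @export
print.brsg_biplot <- function(x, ...) {
  cat("PCA biplot: ", nrow(x$genes), " genes x ", nrow(x$scores),
      " samples\n", sep = "")
  ve <- round(100 * x$var_explained[1:min(2L, length(x$var_explained))], 1)
  cat("  variance explained: PC1 ", ve[1L], "%",
      if (length(ve) > 1L) paste0(", PC2 ", ve[2L], "%"), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname print.brsg_biplot
#' @param x A `"brsg_biplot"`.
#' @param y,... Unused / passed to [graphics::plot()].
plot.brsg_biplot <- function(x, y, ...) {
  rng <- range(c(x$scores[, 1:2], x$genes[, 1:2]))
  graphics::plot(x$genes[, 1L], x$genes[, 2L], col = "red", pch = 20,
                 xlim = rng, ylim = rng,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2L]),
                 ...)
  graphics::points(x$scores[, 1L], x$scores[, 2L], col = "blue", pch = 17)
  graphics::abline(v = 0, h = 0, lty = 3)
  graphics::text(x$scores[, 1L], x$scores[, 2L],
                 labels = rownames(x$scores), pos = 3, cex = 0.7,
                 col = "blue")
  invisible(x)
}

#' Count items by principal-axis side
#'
#' Counts gene or sample coordinates left (`< 0`) and right (`> 0`) of zero
#' on a principal axis. Exact zeros are counted as right and flagged via
#' `n_zero` (a measure-zero event under continuous data).
#'
#' @param biplot A `"brsg_biplot"`.
#' @param items Optional subset of item identifiers; an empty selection is a
#'   hard error.
#' @param what `"genes"` or `"samples"`.
#' @param axis Principal-axis index (default 1).
#' @return List with `n_left`, `n_right`, `n_zero`, `n`, and the `items`
#'   used.
#' @export
side_counts <- function(biplot, items = NULL, what = c("genes", "samples"),
                        axis = 1L) {
  stopifnot(inherits(biplot, "brsg_biplot"))
  what <- match.arg(what)
  coords <- if (what == "genes") biplot$genes else biplot$scores
  ids <- rownames(coords)
  items <- items %||% ids
  items <- intersect(items, ids)
  if (length(items) == 0L) stop("no matching items on the biplot")
  v <- coords[items, axis]
  list(n_left = sum(v < 0), n_right = sum(v >= 0), n_zero = sum(v == 0),
       n = length(v), items = items)
}

#' Exact binomial side-preference test
#'
#' Tests whether `k` successes in `n` trials are compatible with the fair
#' null probability 0.5, by direct summation of the binomial probability
#' mass function: the one-sided p-values are the upper/lower tails at `k`,
#' and the two-sided p-value sums all outcomes whose pmf does not exceed
#' that of `k`. Used on principal-axis side counts, where "success" is
#' landing on a designated side.
#'
#' @param n Number of trials.
#' @param k Number of successes, `0 <= k <= n`.
#' @param alternative `"two.sided"` (default), `"greater"` (upper tail,
#'   `P(X >= k)`) or `"less"` (lower tail).
#' @return Object of class `"brsg_binom"`: list with `n`, `k`, `p0 = 0.5`,
#'   `alternative`, `p_value`.
#' @examples
#' binomial_side_test(18, 18, "greater")  # 0.5^18 = 3.8e-06
#' binomial_side_test(46, 9)              # two-sided, ~4.1e-05
#' @export
binomial_side_test <- function(n, k,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 0, k >= 0, k <= n)
  d <- stats::dbinom(0:n, n, 0.5)
  p <- switch(alternative,
    greater = sum(d[(k + 1L):(n + 1L)]),
    less = sum(d[1:(k + 1L)]),
    two.sided = sum(d[d <= d[k + 1L] * (1 + 1e-07)]))
  p <- min(1, p)
  structure(list(n = n, k = k, p0 = 0.5, alternative = alternative,
                 p_value = p),
            class = "brsg_binom")
}

#' @export
print.brsg_binom <- function(x, ...) {
  cat(sprintf("Exact binomial side test: %d of %d at p0 = 0.5 (%s)\n",
              x$k, x$n, x$alternative))
  cat(sprintf("  p-value = %.3g\n", x$p_value))
  invisible(x)
}

#' Side-preference summary for a biplot subset
#'
#' Convenience wrapper: counts the subset's items by PC-axis side and
#' reports both the two-sided and the upper-tail exact binomial p-values for
#' the right-side count (both sidedness conventions are always reported;
#' which is appropriate depends on whether the direction was specified in
#' advance).
#'
#' @inheritParams side_counts
#' @return One-row data frame: `what`, `axis`, `n`, `n_left`, `n_right`,
#'   `n_zero`, `p_two_sided`, `p_right_ge`.
#' @export
side_preference <- function(biplot, items = NULL,
                            what = c("genes", "samples"), axis = 1L) {
  what <- match.arg(what)
  sc <- side_counts(biplot, items = items, what = what, axis = axis)
  data.frame(what = what, axis = axis, n = sc$n, n_left = sc$n_left,
             n_right = sc$n_right, n_zero = sc$n_zero,
             p_two_sided = binomial_side_test(sc$n, sc$n_right)$p_value,
             p_right_ge = binomial_side_test(sc$n, sc$n_right,
                                             "greater")$p_value,
             stringsAsFactors = FALSE)
}

#' Agglomerative hierarchical clustering of gene profiles
#'
#' Clusters gene expression profiles (optionally standardised per gene) by
#' Euclidean distance under the chosen linkage (Ward by default, via
#' `"ward.D2"`). The merge order of [stats::hclust()] is deterministic given
#' the input (ties merge lowest index first); cluster memberships at a fixed
#' cut are invariant to input order up to relabelling.
#'
#' @param expression Genes-by-samples matrix.
#' @param genes Optional gene subset (>= 2 items).
#' @param k Number of clusters to cut into (exclusive with `h`).
#' @param h Merge height to cut at.
#' @param linkage One of `"ward"`, `"complete"`, `"average"`, `"single"`;
#'   any other name is a hard error.
#' @param standardize Standardise each gene profile first (default `TRUE`).
#' @return Object of class `"brsg_ahc"`: `assignment` (named cluster ids),
#'   `sizes`, `hclust` (the tree), `linkage`, `k`, `h`.
#' @export
ahc_cluster <- function(expression, genes = NULL, k = NULL, h = NULL,
                        linkage = c("ward", "complete", "average", "single"),
                        standardize = TRUE) {
  linkage <- match.arg(linkage)
  method <- c(ward = "ward.D2", complete = "complete", average = "average",
              single = "single")[[linkage]]
  genes <- genes %||% rownames(expression)
  genes <- intersect(genes, rownames(expression))
  if (length(genes) < 2L) stop("need at least 2 genes to cluster")
  prof <- expression[genes, , drop = FALSE]
  if (standardize) {
    sds <- apply(prof, 1L, stats::sd)
    prof <- (prof - rowMeans(prof)) / ifelse(sds > 0, sds, 1)
  }
  hc <- stats::hclust(stats::dist(prof), method = method)
  if (is.null(k) && is.null(h)) k <- 2L
  assignment <- stats::cutree(hc, k = k, h = h)
  structure(list(assignment = assignment,
                 sizes = as.integer(table(assignment)),
                 hclust = hc, linkage = linkage, k = k, h = h),
            class = "brsg_ahc")
}

#' @export
print.brsg_ahc <- function(x, ...) {
  cat("Agglomerative clustering (", x$linkage, " linkage): ",
      length(x$assignment), " items in ", length(x$sizes),
      " cluster(s) of size ", paste(x$sizes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @importFrom graphics abline points text
NULL
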