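# Tabular IO: expression matrices, sample metadata, gene panels, result
# tables. Expression TSV layout is genes-as-rows: a header row of sample ids
# and a first column of gene ids. Missing or non-numeric cells are hard
# errors, never imputed -- silent zero-filling would distort the specificity
# index downstream.

#' Read an FPKM expression matrix from TSV
#'
#' Parses a tab-separated expression table into a numeric genes-by-samples
#' matrix and validates it: identifiers must be unique, every cell must be a
#' non-negative number. Violations are hard errors naming the offending
#' identifier or cell.
#'
#' @param path Path to a TSV file with one header row of sample identifiers
#'   and a first column of gene identifiers.
#' @param genes_as_rows Logical; if `FALSE` the file is transposed on read
#'   (samples in rows, genes in columns).
#' @return Numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names.
#' @seealso [write_expression_tsv()], [read_metadata_tsv()]
#' @export
read_expression_tsv <- function(path, genes_as_rows = TRUE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file needs an id column plus at least one data column: ",
         path)
  ids <- raw[[1L]]
  vals <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   ids[bad[1L]], colnames(vals)[j]))
    mat[, j] <- x
  }
  if (!genes_as_rows) mat <- t(mat)
  validate_expression_matrix(mat)
  mat
}

validate_expression_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must have gene row names and sample column names")
  dup_g <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup_g) > 0L)
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup_s) > 0L)
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative FPKM value at gene '%s', sample '%s'",
                 rownames(mat)[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))
  invisible(mat)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: genes as rows, a `gene_id` id column,
#' sample ids as the remaining header fields. Writing the same matrix twice
#' yields byte-identical files.
#'
#' @param mat Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `region`, `group`. Region and group labels
#' are validated against the declared label sets; unknown labels and
#' duplicate samples are hard errors.
#'
#' @param path Path to a TSV file.
#' @param regions Allowed region labels (default [brain_regions()]).
#' @param groups Allowed group labels (default [stress_groups()]).
#' @return Data frame with columns `sample_id`, `region`, `group`.
#' @export
read_metadata_tsv <- function(path, regions = brain_regions(),
                              groups = stress_groups()) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "region", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  validate_metadata(df, regions = regions, groups = groups)
  df
}

validate_metadata <- function(df, regions, groups) {
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L)
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  bad_r <- setdiff(unique(df$region), regions)
  if (length(bad_r) > 0L)
    stop("unknown region label(s): ", paste(bad_r, collapse = ", "),
         " (declared: ", paste(regions, collapse = ", "), ")")
  bad_g <- setdiff(unique(df$group), groups)
  if (length(bad_g) > 0L)
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "))
  invisible(df)
}

#' Restrict an expression matrix and its metadata to shared samples
#'
#' Both inputs are restricted to the intersection of their sample
#' identifiers; the matrix's original column order is preserved and the
#' metadata is reordered to match. Samples dropped from either side are
#' reported via `message()`. An empty intersection is a hard error. The
#' operation is idempotent.
#'
#' @param expression Genes-by-samples numeric matrix.
#' @param metadata Data frame as returned by [read_metadata_tsv()].
#' @return List with elements `expression` and `metadata`.
#' @export
align_samples <- function(expression, metadata) {
  common <- intersect(colnames(expression), metadata$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and metadata")
  drop_m <- setdiff(colnames(expression), common)
  drop_s <- setdiff(metadata$sample_id, common)
  if (length(drop_m) > 0L)
    message("align_samples: dropped ", length(drop_m),
            " matrix sample(s) absent from metadata: ",
            paste(utils::head(drop_m, 5L), collapse = ", "))
  if (length(drop_s) > 0L)
    message("align_samples: dropped ", length(drop_s),
            " metadata sample(s) absent from matrix: ",
            paste(utils::head(drop_s, 5L), collapse = ", "))
  keep <- colnames(expression)[colnames(expression) %in% common]
  expression <- expression[, keep, drop = FALSE]
  metadata <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(expression = expression, metadata = metadata)
}

#' Write a flat table of records to TSV
#'
#' Deterministic writer used for all package outputs: tab separator, header,
#' no quoting, no row names. When `sort_by` is given, rows are ordered by
#' those columns so repeated writes of logically identical inputs are
#' byte-identical regardless of incoming row order.
#'
#' @param records Data frame.
#' @param path Output path; an unwritable path is a hard error.
#' @param sort_by Optional character vector of column names to sort rows by.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, sort_by = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(sort_by)) {
    miss <- setdiff(sort_by, colnames(records))
    if (length(miss) > 0L)
      stop("sort_by column(s) not in records: ", paste(miss, collapse = ", "))
    records <- records[do.call(order, records[sort_by]), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read gene panel definitions from a long-format TSV
#'
#' Expects columns `panel_name` and `gene_id`, one row per panel member.
#' Panels must be non-empty and duplicate-free.
#'
#' @param path Path to a TSV file.
#' @return Named list of character vectors (one per panel).
#' @seealso [builtin_panels()]
#' @export
read_gene_panels <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("panel_name", "gene_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("panel file lacks column(s): ", paste(miss, collapse = ", "))
  panels <- split(df$gene_id, df$panel_name)
  for (nm in names(panels)) {
    if (anyDuplicated(panels[[nm]]))
      stop("panel '", nm, "' contains duplicate gene(s): ",
           paste(unique(panels[[nm]][duplicated(panels[[nm]])]),
                 collapse = ", "))
    if (length(panels[[nm]]) == 0L) stop("panel '", nm, "' is empty")
  }
  panels
}
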