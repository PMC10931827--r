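# Small deterministic fixtures built in code.

# 2-gene x 3-sample matrix with values 1..6 (column-major fill).
tiny_matrix <- function() {
  matrix(1:6, nrow = 2, dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
}

# Metadata for a design of n replicates per region x group cell.
make_metadata <- function(regions = brain_regions(),
                          groups = stress_groups(), reps = 3) {
  g <- expand.grid(rep = seq_len(reps), group = groups, region = regions,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_%d", g$region, g$group, g$rep),
             region = g$region, group = g$group, stringsAsFactors = FALSE)
}

# Constant-expectation matrix for the given metadata: one row per gene,
# value = base[g] everywhere, optionally elevated in target regions.
make_matrix <- function(meta, base, fold = 1, targets = NULL) {
  n <- length(base)
  genes <- names(base) %||% sprintf("g%03d", seq_len(n))
  m <- matrix(rep(base, times = nrow(meta)), nrow = n,
              dimnames = list(genes, meta$sample_id))
  if (!is.null(targets)) {
    for (i in seq_len(n)) {
      if (!is.na(targets[i]))
        m[i, meta$region == targets[i]] <- m[i, meta$region == targets[i]] *
          fold
    }
  }
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

ref_profile_matrix <- function() {
  d <- vta_mrn_reference()
  m <- as.matrix(d[, c("HPC", "HPT", "STR", "MRN", "VTA")])
  rownames(m) <- d$gene
  m
}
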