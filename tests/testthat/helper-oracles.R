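## Deterministic in-frame CDR3 sequence for clonotype index i: "TGT" plus a
## fixed-width base-4 encoding of i. Distinct i always give distinct keys.
seq_for <- function(i, width = 6L) {
  vapply(i, function(x) {
    digits <- integer(width)
    for (p in seq_len(width)) {
      digits[p] <- x %% 4L
      x <- x %/% 4L
    }
    paste0("TGT", paste(c("A", "C", "G", "T")[digits + 1L], collapse = ""))
  }, character(1))
}

## Repertoire with the given clone sizes, one distinct clonotype per count.
make_rep <- function(counts, frame = "productive",
                     label = list(subset = "test"), start_index = 1L) {
  n <- length(counts)
  repertoire(data.frame(
    cdr3_nt = seq_for(seq.int(start_index, length.out = n)),
    cdr3_aa = NA_character_, v_gene = "TRAV1", j_gene = "TRAJ1",
    templates = as.integer(counts),
    frame = rep_len(frame, n), stringsAsFactors = FALSE),
    label = label)
}

## Independent oracle for Simpson's diversity: enumerate all ordered pairs
## of cells and count the fraction drawn from the same clone.
brute_simpson <- function(counts) {
  cells <- rep(seq_along(counts), counts)
  n <- length(cells)
  same <- sum(outer(cells, cells, "==")) - n
  same / (n * (n - 1))
}

## Exact expectation of subsampled clonality: enumerate every k-subset of
## the clonotypes and average the pair-enumeration clonality. Returns the
## mean and the sd of the per-subset values (for Monte-Carlo error bounds).
exact_subsample_clonality <- function(counts, k) {
  combs <- utils::combn(length(counts), k)
  vals <- apply(combs, 2, function(ix) sqrt(brute_simpson(counts[ix])))
  list(mean = mean(vals), sd = stats::sd(vals), n_subsets = ncol(combs))
}

## Exact expectation of the subsampled Jaccard index: enumerate every pair
## of k-subsets of the two key sets.
exact_subsample_jaccard <- function(keys_a, keys_b, k) {
  ca <- utils::combn(length(keys_a), k)
  cb <- utils::combn(length(keys_b), k)
  vals <- numeric(ncol(ca) * ncol(cb))
  idx <- 0L
  for (i in seq_len(ncol(ca))) {
    a <- keys_a[ca[, i]]
    for (j in seq_len(ncol(cb))) {
      b <- keys_b[cb[, j]]
      inter <- length(intersect(a, b))
      idx <- idx + 1L
      vals[idx] <- inter / (2L * k - inter)
    }
  }
  list(mean = mean(vals), sd = stats::sd(vals), n_pairs = length(vals))
}

## Write a clonotype data.frame as a raw dialect TSV (bypassing the package
## writer) so reader tests have an independent fixture path.
write_raw_airr <- function(df, path) {
  out <- data.frame(junction = df$cdr3_nt,
                    junction_aa = ifelse(is.na(df$cdr3_aa), "", df$cdr3_aa),
                    v_call = df$v_gene, j_call = df$j_gene,
                    duplicate_count = df$templates,
                    productive = df$productive)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
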