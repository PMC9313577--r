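#' @keywords internal
"_PACKAGE"

## Deterministic 31-bit polynomial hash of a string, mixed with a master seed.
## Drives per-repertoire RNG substreams so that pair statistics are symmetric
## in their arguments and independent of evaluation order.
hash_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  m <- 2147483647
  h <- as.double(seed) %% m
  for (b in utf8ToInt(enc2utf8(as.character(label)))) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

## Evaluate expr under a private RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## All 64 codons; the three stop codons are TAA, TAG, TGA.
stop_codons <- c("TAA", "TAG", "TGA")

codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLLLLLIIIMVVVV",
    "SSSSPPPPTTTTAAAA",
    "YY**HHQQNNKKDDEE",
    "CC*WRRRRSSRRGGGG"), "")[[1]]
  ## string is ordered second base slowest, then first base, then third
  second <- rep(bases, each = 16)
  first <- rep(rep(bases, each = 4), 4)
  third <- rep(bases, 16)
  names(aa) <- paste0(first, second, third)
  aa
})

## Split a nucleotide string into codons; incomplete trailing codon kept as-is.
split_codons <- function(nt) {
  n <- nchar(nt)
  starts <- seq.int(1L, n, by = 3L)
  substring(nt, starts, pmin(starts + 2L, n))
}

## TRUE iff length divisible by 3 and no stop codon in frame: the fallback
## rule used when a clonotype's productivity flag is missing.
is_inframe_productive <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || nchar(s) == 0L || nchar(s) %% 3L != 0L) return(FALSE)
    !any(split_codons(s) %in% stop_codons)
  }, logical(1), USE.NAMES = FALSE)
}

## Translate in-frame nucleotide strings ("*" for stop); NA for sequences
## whose length is not a positive multiple of 3. Vectorized by codon
## position.
translate_nt <- function(nt) {
  nt <- as.character(nt)
  len <- nchar(nt)
  ok <- !is.na(nt) & len > 0L & len %% 3L == 0L
  out <- rep(NA_character_, length(nt))
  if (!any(ok)) return(out)
  sub <- nt[ok]
  ncod <- nchar(sub) %/% 3L
  m <- matrix("", length(sub), max(ncod))
  for (j in seq_len(max(ncod))) {
    rows <- ncod >= j
    m[rows, j] <- codon_table[substr(sub[rows], 3L * j - 2L, 3L * j)]
  }
  out[ok] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  out
}

## Normalize marker calls given as 0/1, TRUE/FALSE, or "+"/"-" to logical.
as_marker_logical <- function(x, marker = "marker") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x)))
      stop("marker column '", marker, "' has values outside {0,1}", call. = FALSE)
    return(x == 1)
  }
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("+", "1", "TRUE", "true", "T", "pos")] <- TRUE
  out[x %in% c("-", "−", "0", "FALSE", "false", "F", "neg")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad))
    stop("marker column '", marker, "' has unrecognized values: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
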