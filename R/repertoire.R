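#' Construct a TCR repertoire
#'
#' A repertoire is a labeled collection of unique clonotypes for one
#' (donor, compartment, subset, tissue) sample. Clonotype identity is defined
#' by an identity key — an ordered subset of
#' \code{c("cdr3_nt", "v_gene", "j_gene", "cdr3_aa")} that must contain a CDR3
#' field. Input rows sharing an identity key are merged by summing their
#' template counts, so exports that split one clonotype across rows are
#' handled transparently. The total template count \eqn{N} and the number of
#' unique clonotypes \eqn{R} are computed on construction and always satisfy
#' \eqn{R \le N}.
#'
#' @param clonotypes data.frame with columns \code{cdr3_nt} (IUPAC ACGT,
#'   non-empty), \code{cdr3_aa} (may be \code{NA}), \code{v_gene},
#'   \code{j_gene}, \code{templates} (positive integer) and \code{frame}
#'   (one of \code{"productive"}, \code{"nonproductive"}, \code{"unknown"}).
#' @param label named list or character vector with entries \code{donor},
#'   \code{compartment} (\code{"CD4"} or \code{"CD8"}), \code{subset},
#'   \code{tissue}. Missing entries default to \code{"NA"}.
#' @param identity character vector of key fields; default
#'   \code{c("cdr3_nt", "v_gene", "j_gene")}. Gene-level identity on the
#'   nucleotide CDR3 is the default because nucleotide-level sharing of
#'   nonproductive rearrangements is what marks common clonal origin.
#' @return An object of class \code{"repertoire"}: a list with elements
#'   \code{clonotypes}, \code{label}, \code{identity}, \code{N}, \code{R}.
#' @examples
#' df <- data.frame(cdr3_nt = c("TGTGCT", "TGTGCT", "TGTTCT"),
#'                  cdr3_aa = NA, v_gene = "TRAV1", j_gene = "TRAJ1",
#'                  templates = c(3L, 2L, 1L), frame = "productive")
#' rep <- repertoire(df, label = c(donor = "D1", subset = "naive"))
#' rep$R  # 2 unique clonotypes
#' rep$N  # 6 templates
#' @export
repertoire <- function(clonotypes,
                       label = list(),
                       identity = c("cdr3_nt", "v_gene", "j_gene")) {
  identity <- validate_identity(identity)
  label <- normalize_label(label)
  needed <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "templates", "frame")
  missing_cols <- setdiff(needed, names(clonotypes))
  if (length(missing_cols))
    stop("clonotype table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  clonotypes <- as.data.frame(clonotypes)[needed]
  if (nrow(clonotypes) == 0L)
    stop("repertoire must contain at least one clonotype", call. = FALSE)

  validate_clonotypes(clonotypes)
  clonotypes <- merge_by_key(clonotypes, identity)

  structure(
    list(clonotypes = clonotypes, label = label, identity = identity,
         N = sum(clonotypes$templates), R = nrow(clonotypes)),
    class = "repertoire")
}

validate_identity <- function(identity) {
  allowed <- c("cdr3_nt", "v_gene", "j_gene", "cdr3_aa")
  identity <- as.character(identity)
  if (length(identity) == 0L)
    stop("identity key must name at least one field", call. = FALSE)
  bad <- setdiff(identity, allowed)
  if (length(bad))
    stop("unknown identity key field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!any(c("cdr3_nt", "cdr3_aa") %in% identity))
    stop("identity key must include cdr3_nt or cdr3_aa", call. = FALSE)
  identity
}

normalize_label <- function(label) {
  label <- as.list(label)
  out <- list(donor = "NA", compartment = "NA", subset = "NA", tissue = "NA")
  for (nm in intersect(names(label), names(out)))
    out[[nm]] <- as.character(label[[nm]])
  out
}

label_string <- function(label) {
  paste(label$donor, label$compartment, label$subset, label$tissue, sep = "|")
}

validate_clonotypes <- function(df) {
  if (any(is.na(df$cdr3_nt) | df$cdr3_nt == ""))
    stop("cdr3_nt must be non-empty for every clonotype", call. = FALSE)
  if (any(grepl("[^ACGT]", df$cdr3_nt)))
    stop("cdr3_nt contains non-ACGT characters", call. = FALSE)
  tmpl <- df$templates
  bad <- which(is.na(tmpl) | tmpl < 1 | tmpl != round(tmpl))
  if (length(bad))
    stop("non-positive or non-integer template count at row ", bad[1],
         call. = FALSE)
  if (!all(df$frame %in% c("productive", "nonproductive", "unknown")))
    stop("frame must be 'productive', 'nonproductive' or 'unknown'",
         call. = FALSE)
  invisible(df)
}

## Merge rows sharing an identity key by summing template counts. Row order
## never affects the result: output is sorted by key.
merge_by_key <- function(df, identity) {
  key <- identity_keys(df, identity)
  if (anyDuplicated(key)) {
    tmpl <- rowsum(as.numeric(df$templates), group = key, reorder = TRUE)
    first <- df[!duplicated(key), , drop = FALSE]
    first <- first[order(key[!duplicated(key)]), , drop = FALSE]
    first$templates <- as.integer(tmpl[, 1])
    df <- first
  } else {
    df <- df[order(key), , drop = FALSE]
  }
  df$templates <- as.integer(df$templates)
  rownames(df) <- NULL
  df
}

## Identity key strings for each clonotype row under the active key fields.
identity_keys <- function(df, identity) {
  cols <- lapply(identity, function(f) {
    v <- as.character(df[[f]])
    v[is.na(v)] <- ""
    v
  })
  do.call(paste, c(cols, sep = "\r"))
}

#' Identity-key set of a repertoire
#'
#' @param rep a \code{repertoire}.
#' @return character vector of identity-key strings, one per unique clonotype.
#' @export
repertoire_keys <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  identity_keys(rep$clonotypes, rep$identity)
}

#' @export
print.repertoire <- function(x, ...) {
  cat("TCR repertoire [", label_string(x$label), "]\n", sep = "")
  cat("  unique clonotypes R =", x$R, " total templates N =", x$N, "\n")
  cat("  identity key:", paste(x$identity, collapse = " + "), "\n")
  tab <- table(factor(x$clonotypes$frame,
                      levels = c("productive", "nonproductive", "unknown")))
  cat("  frames:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  cnt <- object$clonotypes$templates
  out <- list(label = label_string(object$label), R = object$R, N = object$N,
              max_clone = max(cnt), singletons = sum(cnt == 1L))
  class(out) <- "summary.repertoire"
  out
}

#' @export
print.summary.repertoire <- function(x, ...) {
  cat("Repertoire", x$label, "- R:", x$R, "N:", x$N,
      "largest clone:", x$max_clone, "singletons:", x$singletons, "\n")
  invisible(x)
}
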