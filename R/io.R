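## Column contracts for the two supported clonotype-table dialects.
## airr:      AIRR Rearrangement TSV (junction, junction_aa, v_call, j_call,
##            duplicate_count, productive with T/F or true/false).
## immunoseq: immunoSEQ-export style TSV (nucleotide, aminoAcid, vGeneName,
##            jGeneName, count — templates / estimatedNumberGenomes accepted —
##            and sequenceStatus / frame_type with In/Out/Stop).
dialect_spec <- function(dialect) {
  switch(dialect,
    airr = list(
      cdr3_nt = "junction", cdr3_aa = "junction_aa",
      v_gene = "v_call", j_gene = "j_call",
      count = "duplicate_count", count_alt = character(0),
      frame = "productive"),
    immunoseq = list(
      cdr3_nt = "nucleotide", cdr3_aa = "aminoAcid",
      v_gene = "vGeneName", j_gene = "jGeneName",
      count = "count", count_alt = c("templates", "estimatedNumberGenomes"),
      frame = "sequenceStatus", frame_alt = "frame_type"),
    stop("unknown dialect: ", dialect, call. = FALSE))
}

#' Read a clonotype table
#'
#' Reads a tab-separated rearrangement file in either the AIRR Rearrangement
#' dialect or an immunoSEQ-export-style dialect, validates it, merges rows
#' that share an identity key (summing template counts), and returns a
#' \code{\link{repertoire}}. Allele suffixes on gene calls
#' (\code{"TRAV12-1*01"} → \code{"TRAV12-1"}) are stripped before keying, so
#' identity is at gene-level resolution.
#'
#' For the immunoSEQ dialect a \code{count} column is preferred;
#' \code{templates} or \code{estimatedNumberGenomes} are accepted in its
#' place, the latter with a warning since read-derived counts are a weaker
#' proxy for cell counts than template quantitation.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect \code{"airr"} or \code{"immunoseq"}.
#' @param identity identity key fields; see \code{\link{repertoire}}.
#' @param label sample label; see \code{\link{repertoire}}.
#' @return a \code{repertoire}.
#' @export
read_clonotype_table <- function(path, dialect = c("airr", "immunoseq"),
                                 identity = c("cdr3_nt", "v_gene", "j_gene"),
                                 label = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- dialect_spec(dialect)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (nrow(df) == 0L)
    stop("no clonotype rows after header in ", path, call. = FALSE)

  pick <- function(primary, alts, what) {
    if (primary %in% names(df)) return(primary)
    for (a in alts) {
      if (a %in% names(df)) {
        if (what == "count" && a == "estimatedNumberGenomes")
          warning("using '", a, "' (reads) because no templates column ",
                  "is present", call. = FALSE)
        return(a)
      }
    }
    stop(dialect, " dialect requires column '", primary, "'", call. = FALSE)
  }
  nt_col <- pick(spec$cdr3_nt, character(0), "cdr3_nt")
  aa_col <- if (spec$cdr3_aa %in% names(df)) spec$cdr3_aa else NA
  v_col <- pick(spec$v_gene, character(0), "v_gene")
  j_col <- pick(spec$j_gene, character(0), "j_gene")
  cnt_col <- pick(spec$count, spec$count_alt, "count")
  fr_col <- pick(spec$frame, spec$frame_alt %||% character(0), "frame")

  counts <- suppressWarnings(as.numeric(df[[cnt_col]]))
  bad <- which(is.na(counts) | counts < 1 | counts != round(counts))
  if (length(bad))
    stop("non-positive or non-integer count '", df[[cnt_col]][bad[1]],
         "' at data row ", bad[1], call. = FALSE)

  frame <- parse_frame(df[[fr_col]], dialect)

  aa <- if (!is.na(aa_col)) df[[aa_col]] else NA_character_
  aa[!is.na(aa) & aa == ""] <- NA_character_
  clon <- data.frame(
    cdr3_nt = toupper(df[[nt_col]]),
    cdr3_aa = aa,
    v_gene = strip_allele(df[[v_col]]),
    j_gene = strip_allele(df[[j_col]]),
    templates = as.integer(counts),
    frame = frame,
    stringsAsFactors = FALSE)
  repertoire(clon, label = label, identity = identity)
}

## "TRAV12-1*01" -> "TRAV12-1": gene-level is the common denominator
## across dialects.
strip_allele <- function(x) sub("\\*.*$", "", x)

parse_frame <- function(x, dialect) {
  x <- trimws(x)
  if (dialect == "airr") {
    out <- rep("unknown", length(x))
    out[x %in% c("T", "TRUE", "true", "True")] <- "productive"
    out[x %in% c("F", "FALSE", "false", "False")] <- "nonproductive"
  } else {
    out <- rep("unknown", length(x))
    out[x %in% c("In", "in")] <- "productive"
    out[x %in% c("Out", "out", "Stop", "stop")] <- "nonproductive"
  }
  out
}

#' Write a clonotype table
#'
#' Writes a repertoire as a TSV in the requested dialect such that
#' \code{read_clonotype_table()} on the written file reproduces the
#' repertoire exactly (round-trip identity). Refuses to write a repertoire
#' with no clonotypes.
#'
#' @param rep a \code{repertoire}.
#' @param path output file path.
#' @param dialect \code{"airr"} or \code{"immunoseq"}.
#' @export
write_clonotype_table <- function(rep, path, dialect = c("airr", "immunoseq")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rep, "repertoire"))
  if (rep$R < 1L) stop("refusing to write an empty repertoire", call. = FALSE)
  df <- rep$clonotypes
  aa <- ifelse(is.na(df$cdr3_aa), "", df$cdr3_aa)
  out <- if (dialect == "airr") {
    data.frame(
      junction = df$cdr3_nt, junction_aa = aa,
      v_call = df$v_gene, j_call = df$j_gene,
      duplicate_count = df$templates,
      productive = c(productive = "T", nonproductive = "F",
                     unknown = "")[df$frame],
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      nucleotide = df$cdr3_nt, aminoAcid = aa,
      vGeneName = df$v_gene, jGeneName = df$j_gene,
      count = df$templates,
      sequenceStatus = c(productive = "In", nonproductive = "Out",
                         unknown = "Unknown")[df$frame],
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("could not write clonotype table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Partition a repertoire by reading frame
#'
#' Splits a repertoire into its productive and nonproductive fractions.
#' Sharing of identical nonproductive rearrangements between subsets marks
#' common clonal origin, because nonproductive sequences are never expressed
#' and hence never selected; the nonproductive fraction is therefore analyzed
#' as a repertoire in its own right.
#'
#' Records with \code{frame = "unknown"} are resolved by the in-frame rule
#' when \code{fallback = TRUE}: productive iff the CDR3 nucleotide length is
#' divisible by 3 and the translation contains no stop codon. With
#' \code{fallback = FALSE} unknowns are routed to the nonproductive output
#' with a warning. Template counts and unique-clonotype counts are conserved:
#' \eqn{N_p + N_{np} = N} always, and the same for \eqn{R} when no identity
#' key collides across frames.
#'
#' @param rep a \code{repertoire}.
#' @param fallback logical; resolve unknown frames by the in-frame rule.
#' @return list with elements \code{productive} and \code{nonproductive}
#'   (either may be \code{NULL} when its fraction is empty).
#' @export
partition_by_frame <- function(rep, fallback = FALSE) {
  stopifnot(inherits(rep, "repertoire"))
  df <- rep$clonotypes
  frame <- df$frame
  unk <- frame == "unknown"
  if (any(unk)) {
    if (isTRUE(fallback)) {
      frame[unk] <- ifelse(is_inframe_productive(df$cdr3_nt[unk]),
                           "productive", "nonproductive")
    } else {
      warning(sum(unk), " clonotype(s) with unknown frame routed to the ",
              "nonproductive fraction", call. = FALSE)
      frame[unk] <- "nonproductive"
    }
  }
  mk <- function(sub, subset_suffix) {
    if (nrow(sub) == 0L) return(NULL)
    repertoire(sub, label = rep$label, identity = rep$identity)
  }
  prod <- df[frame == "productive", , drop = FALSE]
  nonp <- df[frame == "nonproductive", , drop = FALSE]
  prod$frame <- rep_len("productive", nrow(prod))
  nonp$frame <- rep_len("nonproductive", nrow(nonp))
  list(productive = mk(prod), nonproductive = mk(nonp))
}
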