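#' Subset classification schemes
#'
#' Two marker schemes for assigning T cells to the five differentiation
#' subsets (naive, SCM, CM, EM, EMRA):
#'
#' \describe{
#'   \item{analysis}{CD45RA x CCR7 quadrant, with CD95 splitting the
#'     CD45RA+CCR7+ quadrant into naive (CD95-) and stem cell memory
#'     (CD95+): CD45RA-CCR7+ is central memory, CD45RA-CCR7- effector
#'     memory, CD45RA+CCR7- EMRA. CD27/CD28 are descriptive only — they are
#'     heterogeneous on EM cells and implied by the quadrant elsewhere, so
#'     they never change the assignment.}
#'   \item{sorting}{the flow-sorting definitions, which additionally require
#'     CD62L concordant with CCR7 (naive/SCM/CM are CD62L+, EM/EMRA CD62L-);
#'     discordant cells are returned as \code{NA} (unassigned).}
#' }
#'
#' @param name \code{"analysis"} or \code{"sorting"}.
#' @return a \code{subset_scheme} object.
#' @export
subset_scheme <- function(name = c("analysis", "sorting")) {
  name <- match.arg(name)
  markers <- if (name == "analysis") c("CD45RA", "CCR7", "CD95")
             else c("CD45RA", "CCR7", "CD95", "CD62L")
  structure(list(name = name, discriminating = markers,
                 labels = c("naive", "SCM", "CM", "EM", "EMRA")),
            class = "subset_scheme")
}

#' @export
print.subset_scheme <- function(x, ...) {
  cat("Subset scheme '", x$name, "': markers ",
      paste(x$discriminating, collapse = ", "), " -> ",
      paste(x$labels, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Classify cells into T-cell differentiation subsets
#'
#' Vectorized classification of boolean marker calls into
#' naive / SCM / CM / EM / EMRA. Marker columns may hold logicals, 0/1, or
#' "+"/"-". The mapping is exhaustive and exclusive over the discriminating
#' markers: every combination of CD45RA, CCR7 and CD95 yields exactly one
#' label (CD95 is only consulted inside the CD45RA+CCR7+ quadrant). Under
#' the sorting scheme, cells whose CD62L call disagrees with CCR7 get
#' \code{NA}.
#'
#' @param cells data.frame with one row per cell and the scheme's
#'   discriminating marker columns.
#' @param scheme a \code{\link{subset_scheme}} (default \code{"analysis"}).
#' @return character vector of subset labels (or \code{NA} for unassigned
#'   cells under the sorting scheme).
#' @examples
#' cells <- data.frame(CD45RA = c(1, 1, 0, 0, 1), CCR7 = c(1, 1, 1, 0, 0),
#'                     CD95 = c(0, 1, 0, 0, 0))
#' classify_cells(cells)  # naive SCM CM EM EMRA
#' @export
classify_cells <- function(cells, scheme = subset_scheme("analysis")) {
  stopifnot(inherits(scheme, "subset_scheme"))
  for (m in scheme$discriminating) {
    if (!m %in% names(cells))
      stop("cells lack discriminating marker column '", m, "'", call. = FALSE)
  }
  ra <- as_marker_logical(cells$CD45RA, "CD45RA")
  ccr7 <- as_marker_logical(cells$CCR7, "CCR7")
  cd95 <- as_marker_logical(cells$CD95, "CD95")
  if (anyNA(ra) || anyNA(ccr7))
    stop("CD45RA/CCR7 calls contain missing values", call. = FALSE)
  if (any(is.na(cd95) & ra & ccr7))
    stop("CD95 call missing for a CD45RA+CCR7+ cell", call. = FALSE)

  out <- character(nrow(cells))
  out[ra & ccr7 & !cd95] <- "naive"
  out[ra & ccr7 & cd95] <- "SCM"
  out[!ra & ccr7] <- "CM"
  out[!ra & !ccr7] <- "EM"
  out[ra & !ccr7] <- "EMRA"

  if (scheme$name == "sorting") {
    cd62l <- as_marker_logical(cells$CD62L, "CD62L")
    if (anyNA(cd62l))
      stop("CD62L calls contain missing values (required by the sorting ",
           "scheme)", call. = FALSE)
    discordant <- cd62l != ccr7
    if (any(discordant)) {
      message(sum(discordant),
              " cell(s) with CCR7/CD62L-discordant calls left unassigned")
      out[discordant] <- NA_character_
    }
  }
  out
}

#' @rdname classify_cells
#' @param cell single-row data.frame (or list coercible to one).
#' @export
classify_cell <- function(cell, scheme = subset_scheme("analysis")) {
  classify_cells(as.data.frame(cell), scheme)[1]
}

#' Flag recent thymic emigrants
#'
#' A recent thymic emigrant (RTE) is operationally a CD21+ naive T cell.
#' CD21 on antigen-experienced (memory) cells is a separate phenomenon and
#' never flags RTE; see \code{\link{cd21_memory_fraction}}.
#'
#' @param cells data.frame with the classification markers plus \code{CD21}.
#' @param scheme a \code{\link{subset_scheme}}.
#' @return logical vector: \code{TRUE} iff the cell classifies as naive and
#'   is CD21+.
#' @export
flag_rte <- function(cells, scheme = subset_scheme("analysis")) {
  if (!"CD21" %in% names(cells))
    stop("CD21 marker column required to flag RTE cells", call. = FALSE)
  subset <- classify_cells(cells, scheme)
  cd21 <- as_marker_logical(cells$CD21, "CD21")
  if (anyNA(cd21)) stop("CD21 calls contain missing values", call. = FALSE)
  !is.na(subset) & subset == "naive" & cd21
}

group_cols <- c("donor_id", "tissue", "compartment")

check_metadata <- function(cells) {
  miss <- setdiff(c(group_cols, "age_years"), names(cells))
  if (length(miss))
    stop("cells lack metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(cells)
}

group_meta <- function(cells) {
  meta <- unique(cells[c(group_cols, "age_years",
                         intersect("cmv_status", names(cells)))])
  if (!"cmv_status" %in% names(meta)) meta$cmv_status <- "unknown"
  meta
}

#' Subset frequencies per donor, tissue and compartment
#'
#' Classifies every cell, then tabulates the frequency of each of the five
#' subsets within each (donor, tissue, compartment) group. Groups with fewer
#' than \code{min_cells} classified cells (default 100) are excluded with a
#' warning, mirroring the exclusion of under-sampled specimens from
#' downstream analysis. Under the sorting scheme, unassigned
#' (CCR7/CD62L-discordant) cells are dropped before the denominator is
#' formed. Within every retained group the five frequencies sum to 1.
#'
#' @param cells data.frame of cells with marker columns plus metadata
#'   \code{donor_id}, \code{age_years}, \code{tissue}, \code{compartment}
#'   (and optionally \code{cmv_status}).
#' @param scheme a \code{\link{subset_scheme}}.
#' @param min_cells minimum cells per group (default 100).
#' @return a \code{cohort_table} data.frame with one row per
#'   (donor, tissue, compartment, subset): columns \code{n_cells},
#'   \code{frequency}, \code{n_total_compartment} plus metadata.
#' @export
cohort_frequencies <- function(cells, scheme = subset_scheme("analysis"),
                               min_cells = 100L) {
  if (NROW(cells) == 0L) stop("no cells supplied", call. = FALSE)
  check_metadata(cells)
  subset <- classify_cells(cells, scheme)
  keep <- !is.na(subset)
  cells <- cells[keep, , drop = FALSE]
  subset <- subset[keep]

  grp <- interaction(cells$donor_id, cells$tissue, cells$compartment,
                     drop = TRUE, sep = "\r")
  labels <- subset_scheme("analysis")$labels
  tab <- table(grp, factor(subset, levels = labels))
  totals <- rowSums(tab)

  small <- totals < min_cells
  if (any(small))
    warning(sum(small), " group(s) with fewer than ", min_cells,
            " cells excluded: ",
            paste(gsub("\r", "/", rownames(tab)[small]), collapse = ", "),
            call. = FALSE)
  tab <- tab[!small, , drop = FALSE]
  totals <- totals[!small]
  if (nrow(tab) == 0L)
    stop("no group reaches min_cells = ", min_cells, call. = FALSE)

  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(
    donor_id = rep(parts[, 1], each = length(labels)),
    tissue = rep(parts[, 2], each = length(labels)),
    compartment = rep(parts[, 3], each = length(labels)),
    subset = rep(labels, times = nrow(tab)),
    n_cells = as.integer(t(tab)),
    n_total_compartment = rep(as.integer(totals), each = length(labels)),
    stringsAsFactors = FALSE)
  out$frequency <- out$n_cells / out$n_total_compartment

  meta <- group_meta(cells)
  out <- merge(out, meta, by = group_cols, sort = FALSE)
  out <- out[order(out$donor_id, out$tissue, out$compartment,
                   match(out$subset, labels)), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Ki67+ (cycling) fraction per subset
#'
#' Fraction of Ki67+ cells within each (donor, tissue, compartment, subset)
#' group — the subset's turnover estimate. Groups below \code{min_cells} are
#' retained but flagged \code{low_confidence}, because the cycling fraction
#' of a rare subset is still informative yet must be interpreted with
#' caution.
#'
#' @inheritParams cohort_frequencies
#' @return data.frame with \code{ki67_fraction}, \code{n_cells} and
#'   \code{low_confidence} per group; empty groups are absent.
#' @export
ki67_by_subset <- function(cells, scheme = subset_scheme("analysis"),
                           min_cells = 100L) {
  if (NROW(cells) == 0L) stop("no cells supplied", call. = FALSE)
  check_metadata(cells)
  if (!"Ki67" %in% names(cells))
    stop("Ki67 marker column required", call. = FALSE)
  subset <- classify_cells(cells, scheme)
  ki67 <- as_marker_logical(cells$Ki67, "Ki67")
  keep <- !is.na(subset)
  cells <- cells[keep, , drop = FALSE]; subset <- subset[keep]
  ki67 <- ki67[keep]

  key <- paste(cells$donor_id, cells$tissue, cells$compartment, subset,
               sep = "\r")
  n <- as.vector(rowsum(rep(1L, length(key)), key))
  pos <- as.vector(rowsum(as.integer(ki67), key))
  parts <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  out <- data.frame(
    donor_id = parts[, 1], tissue = parts[, 2], compartment = parts[, 3],
    subset = parts[, 4], n_cells = n, ki67_fraction = pos / n,
    low_confidence = n < min_cells, stringsAsFactors = FALSE)
  out <- merge(out, group_meta(cells), by = group_cols, sort = FALSE)
  rownames(out) <- NULL
  out
}

#' CD21+ fraction among memory (non-naive) cells
#'
#' Fraction of CD21+ cells among cells classified SCM/CM/EM/EMRA within each
#' (donor, tissue, compartment) group. CD21 on memory cells is reported
#' separately from the RTE (CD21+ naive) phenotype. Groups with no memory
#' cells are absent from the output.
#'
#' @inheritParams cohort_frequencies
#' @return data.frame with \code{cd21_memory_fraction} and \code{n_memory}
#'   per group.
#' @export
cd21_memory_fraction <- function(cells, scheme = subset_scheme("analysis")) {
  if (NROW(cells) == 0L) stop("no cells supplied", call. = FALSE)
  check_metadata(cells)
  if (!"CD21" %in% names(cells))
    stop("CD21 marker column required", call. = FALSE)
  subset <- classify_cells(cells, scheme)
  cd21 <- as_marker_logical(cells$CD21, "CD21")
  keep <- !is.na(subset) & subset != "naive"
  if (!any(keep))
    return(data.frame(donor_id = character(0), tissue = character(0),
                      compartment = character(0), n_memory = integer(0),
                      cd21_memory_fraction = numeric(0)))
  cells <- cells[keep, , drop = FALSE]; cd21 <- cd21[keep]
  key <- paste(cells$donor_id, cells$tissue, cells$compartment, sep = "\r")
  n <- as.vector(rowsum(rep(1L, length(key)), key))
  pos <- as.vector(rowsum(as.integer(cd21), key))
  parts <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  out <- data.frame(
    donor_id = parts[, 1], tissue = parts[, 2], compartment = parts[, 3],
    n_memory = n, cd21_memory_fraction = pos / n, stringsAsFactors = FALSE)
  out <- merge(out, group_meta(cells), by = group_cols, sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a per-cell marker-call table
#'
#' Delimited text, one row per cell: metadata columns (\code{donor_id},
#' \code{age_years}, \code{tissue}, \code{cmv_status}, \code{compartment})
#' plus marker columns holding \code{0/1} or \code{+/-}.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @return data.frame of cells.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  check_metadata(df)
  df
}
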