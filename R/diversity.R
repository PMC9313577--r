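#' Simpson's diversity index of a clone-size vector
#'
#' \deqn{D = \sum_i n_i (n_i - 1) / (N (N - 1))}
#' where \eqn{n_i} is the template (cell) count of clonotype \eqn{i} and
#' \eqn{N = \sum_i n_i}. This is the probability that two cells drawn without
#' replacement from the sample carry the same clonotype: 0 for a fully
#' polyclonal sample (all singletons), 1 for a monoclonal one.
#'
#' @param counts vector of positive integer clone sizes; \eqn{N \ge 2}.
#' @return a number in \eqn{[0, 1]}.
#' @examples
#' simpson_diversity(c(2, 1, 1))  # 2/12
#' @export
simpson_diversity <- function(counts) {
  counts <- check_counts(counts)
  n_tot <- sum(counts)
  if (n_tot < 2)
    stop("Simpson's diversity is undefined for N < 2", call. = FALSE)
  sum(counts * (counts - 1)) / (n_tot * (n_tot - 1))
}

#' Simpson's clonality index
#'
#' The square root of \code{\link{simpson_diversity}}. Close to zero in
#' highly diverse samples; higher in oligoclonal ones; exactly 1 for a
#' monoclonal repertoire.
#'
#' @inheritParams simpson_diversity
#' @return a number in \eqn{[0, 1]}.
#' @export
simpson_clonality <- function(counts) {
  sqrt(simpson_diversity(counts))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(is.na(counts) | counts < 1 |
                                  counts != round(counts)))
    stop("clone sizes must be positive integers", call. = FALSE)
  counts
}

#' Jaccard index of two clonotype sets
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|} on two sets of clonotype identity
#' keys. Abundance is ignored: overlap is a property of the unique-clonotype
#' sets. For two fully overlapping repertoires the Jaccard index is one; for
#' disjoint repertoires it is zero.
#'
#' @param set_a,set_b non-empty vectors of identity keys (duplicates ignored),
#'   or \code{repertoire} objects whose key sets are used.
#' @return a number in \eqn{[0, 1]}, symmetric in its arguments.
#' @export
jaccard_index <- function(set_a, set_b) {
  if (inherits(set_a, "repertoire")) set_a <- repertoire_keys(set_a)
  if (inherits(set_b, "repertoire")) set_b <- repertoire_keys(set_b)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("Jaccard index is undefined for an empty set", call. = FALSE)
  inter <- length(intersect(set_a, set_b))
  inter / (length(set_a) + length(set_b) - inter)
}

#' Subsample a repertoire to k unique clonotypes
#'
#' Draws exactly \code{k} clonotype records uniformly at random without
#' replacement from the repertoire's unique records, retaining their template
#' counts. This is the normalization unit used throughout: repertoires are
#' compared after subsampling the larger ones to the unique-clonotype count
#' of the smallest. \code{k = R} returns the input repertoire unchanged.
#'
#' @param rep a \code{repertoire}.
#' @param k integer, \eqn{1 \le k \le R}.
#' @return a \code{repertoire} with \code{R = k}.
#' @export
subsample_unique <- function(rep, k) {
  stopifnot(inherits(rep, "repertoire"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (k > rep$R)
    stop("k = ", k, " exceeds the ", rep$R, " unique clonotypes of [",
         label_string(rep$label), "]", call. = FALSE)
  if (k == rep$R) return(rep)
  idx <- sample.int(rep$R, k)
  repertoire(rep$clonotypes[idx, , drop = FALSE],
             label = rep$label, identity = rep$identity)
}

#' Subsample-normalized Simpson's clonality
#'
#' Repeatedly subsamples a repertoire to \code{k} unique clonotypes and
#' averages \code{\link{simpson_clonality}} over the subsamples. This
#' normalizes clonality for unequal sample sizes and sequencing depths when
#' comparing populations: larger repertoires are subsampled to the
#' unique-clonotype count of the smallest population in the comparison
#' (default 100 000 iterations). The repertoire whose \eqn{R} equals \code{k}
#' is used as-is, giving zero resampling variance.
#'
#' Results are deterministic given \code{seed}: the RNG substream is derived
#' from the seed and the repertoire label, so the value does not depend on
#' what else was computed before.
#'
#' @param rep a \code{repertoire}.
#' @param k subsample size in unique clonotypes, \eqn{1 \le k \le R}.
#' @param n_iter number of resampling iterations (default 1e5).
#' @param seed integer master seed.
#' @return a \code{diversity_result}: statistic name, full-sample
#'   \code{point_value}, \code{resampled_mean}, \code{resampled_sd},
#'   \code{k}, \code{n_iter}, \code{seed} and the source label.
#' @export
resampled_clonality <- function(rep, k, n_iter = 100000L, seed = 1L) {
  stopifnot(inherits(rep, "repertoire"))
  k <- as.integer(k); n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (k > rep$R)
    stop("k = ", k, " exceeds the ", rep$R, " unique clonotypes of [",
         label_string(rep$label), "]", call. = FALSE)

  counts <- rep$clonotypes$templates
  point <- simpson_clonality(counts)
  if (k == rep$R) {
    vals <- rep_len(point, 1L)
    res_mean <- point; res_sd <- 0
  } else {
    sub_seed <- hash_seed(seed, paste0("clonality|", label_string(rep$label)))
    vals <- with_seed(sub_seed, {
      vapply(seq_len(n_iter), function(i) {
        simpson_clonality(counts[sample.int(rep$R, k)])
      }, numeric(1))
    })
    res_mean <- mean(vals)
    res_sd <- if (n_iter > 1L) stats::sd(vals) else 0
  }
  structure(
    list(statistic = "simpson_clonality", point_value = point,
         resampled_mean = res_mean, resampled_sd = res_sd,
         k = k, n_iter = n_iter, seed = as.integer(seed),
         source_label = label_string(rep$label)),
    class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Simpson's clonality [", x$source_label, "]\n", sep = "")
  cat(sprintf("  point value: %.6g\n", x$point_value))
  cat(sprintf("  resampled (k=%d, %d iter, seed %d): mean %.6g, sd %.3g\n",
              x$k, x$n_iter, x$seed, x$resampled_mean, x$resampled_sd))
  invisible(x)
}

#' Subsample-normalized Jaccard overlap of two repertoires
#'
#' At each iteration both repertoires are independently subsampled to
#' \code{k} unique clonotypes (a repertoire with \eqn{R = k} is used as-is)
#' and the Jaccard index of the resulting identity-key sets is computed; the
#' mean and standard deviation over iterations are reported, along with the
#' full-sample intersection size.
#'
#' RNG substreams are derived per (seed, repertoire label), so the result is
#' symmetric under swapping the two arguments and reproducible regardless of
#' evaluation order.
#'
#' @param rep_a,rep_b \code{repertoire}s sharing an identity-key definition.
#' @param k subsample size, \eqn{k \le \min(R_A, R_B)}.
#' @param n_iter iterations (default 1e5).
#' @param seed integer master seed.
#' @return an \code{overlap_result}.
#' @export
resampled_jaccard <- function(rep_a, rep_b, k, n_iter = 100000L, seed = 1L) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  k <- as.integer(k); n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  for (r in list(rep_a, rep_b))
    if (k > r$R)
      stop("k = ", k, " exceeds the ", r$R, " unique clonotypes of [",
           label_string(r$label), "]", call. = FALSE)

  keys_a <- repertoire_keys(rep_a)
  keys_b <- repertoire_keys(rep_b)
  n_shared_full <- length(intersect(keys_a, keys_b))

  ## map keys into a common integer universe once; per-iteration work is
  ## then integer subsampling + intersection
  universe <- unique(c(keys_a, keys_b))
  ids_a <- match(keys_a, universe)
  ids_b <- match(keys_b, universe)
  r_a <- length(ids_a); r_b <- length(ids_b)

  ## each repertoire owns an RNG substream keyed by (seed, its label), kept
  ## as a saved .Random.seed state and advanced only by its own draws: the
  ## result is symmetric in the argument order
  vals <- with_seed(seed, {
    env <- globalenv()
    state_for <- function(lab) {
      set.seed(hash_seed(seed, paste0("jaccard|", lab)))
      get(".Random.seed", envir = env)
    }
    st_a <- if (r_a > k) state_for(label_string(rep_a$label))
    st_b <- if (r_b > k) state_for(label_string(rep_b$label))
    out <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      if (r_a > k) {
        assign(".Random.seed", st_a, envir = env)
        a <- ids_a[sample.int(r_a, k)]
        st_a <- get(".Random.seed", envir = env)
      } else a <- ids_a
      if (r_b > k) {
        assign(".Random.seed", st_b, envir = env)
        b <- ids_b[sample.int(r_b, k)]
        st_b <- get(".Random.seed", envir = env)
      } else b <- ids_b
      inter <- length(intersect(a, b))
      out[i] <- inter / (2L * k - inter)
    }
    out
  })

  structure(
    list(jaccard_mean = mean(vals),
         jaccard_sd = if (n_iter > 1L) stats::sd(vals) else 0,
         k = k, n_iter = n_iter, seed = as.integer(seed),
         labels = c(label_string(rep_a$label), label_string(rep_b$label)),
         n_shared_full = n_shared_full),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Jaccard overlap [", x$labels[1], "] vs [", x$labels[2], "]\n", sep = "")
  cat(sprintf("  resampled (k=%d, %d iter, seed %d): mean %.6g, sd %.3g\n",
              x$k, x$n_iter, x$seed, x$jaccard_mean, x$jaccard_sd))
  cat("  full-sample shared clonotypes:", x$n_shared_full, "\n")
  invisible(x)
}

#' Pairwise subsample-normalized overlap matrix
#'
#' Computes \code{\link{resampled_jaccard}} for every pair of repertoires
#' after restricting each to the requested frame, with the common subsample
#' size \code{k} set to the smallest unique-clonotype count across the
#' included repertoires. Repertoires left empty by the frame filter are
#' excluded with a warning.
#'
#' @param reps named list of \code{repertoire}s (>= 2 after filtering).
#' @param n_iter iterations per pair.
#' @param seed master seed.
#' @param frame \code{"productive"} or \code{"nonproductive"}; frames are
#'   resolved with the in-frame fallback rule (see
#'   \code{\link{partition_by_frame}}).
#' @return an \code{overlap_matrix}: list with the mean matrix \code{jaccard}
#'   (diagonal 1), \code{sd} matrix, \code{k}, \code{n_iter}, \code{seed},
#'   \code{frame}, and the list of pairwise \code{overlap_result}s.
#' @export
pairwise_overlap_matrix <- function(reps, n_iter = 100000L, seed = 1L,
                                    frame = c("productive", "nonproductive")) {
  frame <- match.arg(frame)
  stopifnot(is.list(reps))
  nm <- names(reps) %||% paste0("rep", seq_along(reps))
  nm[nm == ""] <- paste0("rep", which(nm == ""))

  kept <- list()
  for (i in seq_along(reps)) {
    part <- partition_by_frame(reps[[i]], fallback = TRUE)
    fr <- part[[frame]]
    if (is.null(fr) || fr$R < 1L) {
      warning("repertoire '", nm[i], "' has no ", frame,
              " clonotypes; excluded", call. = FALSE)
    } else {
      kept[[nm[i]]] <- fr
    }
  }
  if (length(kept) < 2L)
    stop("need at least two repertoires with ", frame, " clonotypes",
         call. = FALSE)

  k <- min(vapply(kept, function(r) r$R, integer(1)))
  p <- length(kept)
  jac <- diag(1, p); sdm <- matrix(0, p, p)
  dimnames(jac) <- dimnames(sdm) <- list(names(kept), names(kept))
  results <- list()
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      res <- resampled_jaccard(kept[[i]], kept[[j]], k = k,
                               n_iter = n_iter, seed = seed)
      jac[i, j] <- jac[j, i] <- res$jaccard_mean
      sdm[i, j] <- sdm[j, i] <- res$jaccard_sd
      results[[paste(names(kept)[i], names(kept)[j], sep = "~")]] <- res
    }
  }
  structure(list(jaccard = jac, sd = sdm, k = k, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), frame = frame, pairs = results),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise Jaccard overlap (", x$frame, " frame, k=", x$k,
      ", ", x$n_iter, " iter, seed ", x$seed, ")\n", sep = "")
  print(round(x$jaccard, digits))
  invisible(x)
}
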