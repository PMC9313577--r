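## --- synthetic CDR3 sequences ------------------------------------------

nonstop_codons <- local({
  bases <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, stop_codons)
})

trav_genes <- paste0("TRAV", 1:40)
traj_genes <- paste0("TRAJ", 1:56)

## n random in-frame CDR3 nucleotide sequences: a fixed TGT (Cys) first
## codon then 9-15 random non-stop codons. Structurally valid placeholders,
## not a model of V(D)J recombination.
random_cdr3 <- function(n, min_codons = 10L, max_codons = 16L) {
  if (n == 0L) return(character(0))
  ncod <- sample.int(max_codons - min_codons + 1L, n, replace = TRUE) +
    min_codons - 1L
  m <- matrix("", n, max_codons)
  m[, 1] <- "TGT"
  for (j in 2:max_codons) {
    rows <- ncod >= j
    if (any(rows))
      m[rows, j] <- sample(nonstop_codons, sum(rows), replace = TRUE)
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## corrupt an in-frame sequence into a nonproductive one: replace a random
## internal codon with a stop, or knock it out of frame by deleting one
## nucleotide
corrupt_to_nonproductive <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  mode_stop <- stats::runif(length(nt)) < 0.5
  out <- nt
  for (i in seq_along(nt)) {
    ncod <- nchar(nt[i]) %/% 3L
    if (mode_stop[i]) {
      pos <- sample.int(ncod - 1L, 1L) + 1L  # never the leading Cys
      substr(out[i], 3L * pos - 2L, 3L * pos) <-
        sample(stop_codons, 1L)
    } else {
      cut <- sample.int(nchar(nt[i]), 1L)
      out[i] <- paste0(substr(nt[i], 1L, cut - 1L),
                       substr(nt[i], cut + 1L, nchar(nt[i])))
    }
  }
  out
}

## n unique in-frame sequences (deduplicated, topped up as needed)
unique_cdr3 <- function(n, min_codons = 10L, max_codons = 16L) {
  space <- length(nonstop_codons)^min_codons
  if (n > space / 100)
    stop("n_unique = ", n, " is too large for the CDR3 sequence space",
         call. = FALSE)
  seqs <- unique(random_cdr3(n, min_codons, max_codons))
  while (length(seqs) < n) {
    seqs <- unique(c(seqs, random_cdr3(n - length(seqs),
                                       min_codons, max_codons)))
  }
  seqs[seq_len(n)]
}

draw_counts <- function(n, law = c("zipf", "geometric", "uniform"),
                        param = 3, max_count = 10000L,
                        n_templates_target = NULL) {
  law <- match.arg(law)
  switch(law,
    zipf = {
      if (param <= 1) stop("zipf exponent must exceed 1", call. = FALSE)
      sizes <- seq_len(max_count)
      sample(sizes, n, replace = TRUE, prob = sizes^(-param))
    },
    geometric = {
      if (param <= 0 || param > 1)
        stop("geometric p must be in (0, 1]", call. = FALSE)
      stats::rgeom(n, param) + 1L
    },
    uniform = {
      per <- if (is.null(n_templates_target)) 1L
             else max(1L, round(n_templates_target / n))
      rep.int(as.integer(per), n)
    })
}

#' Generate a synthetic TCR repertoire
#'
#' Produces a repertoire of \code{n_unique} distinct productive clonotypes
#' with random structurally valid CDR3 nucleotide sequences (length divisible
#' by 3, no stop codons, leading Cys codon) and clone sizes drawn from a
#' chosen law. A heavy-tailed zipf law (\eqn{P(n_i = c) \propto c^{-a}}) is
#' the default, emulating the skewed clone-size distributions of real
#' repertoires; \code{"uniform"} gives equal counts and \code{"geometric"} an
#' intermediate tail. Each productive clonotype independently carries a
#' paired nonproductive rearrangement (a stop-codon-bearing or out-of-frame
#' copy of a second allele) with probability \code{nonproductive_rate};
#' these enter the repertoire as \code{frame = "nonproductive"} records with
#' the clone's template count.
#'
#' Output is deterministic given \code{seed}.
#'
#' @param n_unique number of distinct productive clonotypes.
#' @param clone_size_law \code{"zipf"}, \code{"geometric"} or
#'   \code{"uniform"}.
#' @param law_param zipf exponent (> 1) or geometric p.
#' @param nonproductive_rate probability a clone carries a paired
#'   nonproductive rearrangement (default 0.15).
#' @param n_templates_target for the uniform law only: total template count
#'   to aim for.
#' @param seed integer seed.
#' @param label repertoire label (see \code{\link{repertoire}}).
#' @param identity identity key fields.
#' @return a \code{repertoire}.
#' @export
generate_repertoire <- function(n_unique,
                                clone_size_law = c("zipf", "geometric",
                                                   "uniform"),
                                law_param = 3,
                                nonproductive_rate = 0.15,
                                n_templates_target = NULL,
                                seed = 1L,
                                label = list(subset = "sim"),
                                identity = c("cdr3_nt", "v_gene", "j_gene")) {
  clone_size_law <- match.arg(clone_size_law)
  n_unique <- as.integer(n_unique)
  if (is.na(n_unique) || n_unique < 1L)
    stop("n_unique must be a positive integer", call. = FALSE)
  if (nonproductive_rate < 0 || nonproductive_rate > 1)
    stop("nonproductive_rate must lie in [0, 1]", call. = FALSE)

  with_seed(seed, {
    nt <- unique_cdr3(n_unique)
    v <- sample(trav_genes, n_unique, replace = TRUE)
    j <- sample(traj_genes, n_unique, replace = TRUE)
    counts <- draw_counts(n_unique, clone_size_law, law_param,
                          n_templates_target = n_templates_target)
    prod <- data.frame(cdr3_nt = nt, cdr3_aa = translate_nt(nt),
                       v_gene = v, j_gene = j,
                       templates = as.integer(counts),
                       frame = "productive", stringsAsFactors = FALSE)
    has_np <- stats::runif(n_unique) < nonproductive_rate
    if (any(has_np)) {
      np_nt <- corrupt_to_nonproductive(nt[has_np])
      np <- data.frame(cdr3_nt = np_nt, cdr3_aa = NA_character_,
                       v_gene = sample(trav_genes, sum(has_np), TRUE),
                       j_gene = sample(traj_genes, sum(has_np), TRUE),
                       templates = as.integer(counts[has_np]),
                       frame = "nonproductive", stringsAsFactors = FALSE)
      prod <- rbind(prod, np)
    }
    repertoire(prod, label = label, identity = identity)
  })
}

## --- subset families with planted overlap ------------------------------

#' Default family specification
#'
#' Unique-clonotype scales and clone-size-law exponents mirroring the
#' asymmetry of real sorted-subset repertoires (stem cell memory samples in
#' the hundreds of clonotypes, naive samples in the tens of thousands), plus
#' a planted overlap matrix in which sharing is highest between the central
#' and effector memory pools, intermediate between SCM and CM, and near zero
#' between naive and any memory subset.
#'
#' @return list with \code{n_unique}, \code{zipf_exponent} and
#'   \code{shared_fraction} entries.
#' @export
default_family_spec <- function() {
  subsets <- c("naive", "SCM", "CM", "EM")
  shared <- diag(1, 4)
  dimnames(shared) <- list(subsets, subsets)
  shared["CM", "EM"] <- shared["EM", "CM"] <- 0.30
  shared["SCM", "CM"] <- shared["CM", "SCM"] <- 0.15
  shared["SCM", "EM"] <- shared["EM", "SCM"] <- 0.08
  shared["naive", "SCM"] <- shared["SCM", "naive"] <- 0.01
  shared["naive", "CM"] <- shared["CM", "naive"] <- 0.01
  shared["naive", "EM"] <- shared["EM", "naive"] <- 0.01
  list(
    n_unique = c(naive = 40000L, SCM = 500L, CM = 30000L, EM = 20000L),
    zipf_exponent = c(naive = 3.0, SCM = 3.0, CM = 2.8, EM = 2.3),
    shared_fraction = shared)
}

#' Generate a family of subset repertoires with planted sharing
#'
#' Builds one repertoire per T-cell subset such that, for every pair of
#' subsets, the number of shared unique clonotypes is exactly
#' \code{round(shared_fraction[i, j] * min(n_i, n_j))} — sharing is
#' constructed at the clonotype-set level, not sampled, so the overlap
#' ground truth is noiseless and any scatter seen downstream is the
#' estimator's own. Shared clonotypes keep the same CDR3/V/J identity (and,
#' when present, the same paired nonproductive rearrangement) in every
#' subset carrying them, so productive and nonproductive sharing mark the
#' same planted clonal origins; non-shared clones never share nonproductive
#' partners. Clone sizes are drawn independently per subset from its zipf
#' law.
#'
#' @param n_unique named integer vector: productive clonotypes per subset.
#' @param shared_fraction symmetric matrix (diagonal 1) of planted shared
#'   fractions of the smaller subset in each pair.
#' @param zipf_exponent named numeric vector of clone-size exponents.
#' @param nonproductive_rate probability a clonotype carries a paired
#'   nonproductive rearrangement.
#' @param seed integer seed.
#' @param donor,compartment,tissue label metadata applied to every subset.
#' @return named list of \code{repertoire}s.
#' @export
generate_subset_family <- function(n_unique = default_family_spec()$n_unique,
                                   shared_fraction =
                                     default_family_spec()$shared_fraction,
                                   zipf_exponent =
                                     default_family_spec()$zipf_exponent,
                                   nonproductive_rate = 0.15,
                                   seed = 1L,
                                   donor = "sim1", compartment = "CD4",
                                   tissue = "MLN") {
  subsets <- names(n_unique)
  if (is.null(subsets)) stop("n_unique must be named by subset", call. = FALSE)
  p <- length(subsets)
  stopifnot(is.matrix(shared_fraction),
            all(dim(shared_fraction) == c(p, p)))
  sf <- shared_fraction[subsets, subsets]
  if (any(abs(sf - t(sf)) > 1e-12) || any(diag(sf) != 1) ||
      any(sf < 0 | sf > 1))
    stop("shared_fraction must be symmetric with unit diagonal and entries ",
         "in [0, 1]", call. = FALSE)

  ## pairwise-disjoint shared pools: n shared for pair (i,j) is the planted
  ## fraction of the smaller subset
  n_shared <- matrix(0L, p, p, dimnames = list(subsets, subsets))
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    n_shared[i, j] <- n_shared[j, i] <-
      as.integer(round(sf[i, j] * min(n_unique[i], n_unique[j])))
  }
  committed <- rowSums(n_shared)
  infeasible <- committed > n_unique
  if (any(infeasible))
    stop("sharing constraints infeasible for subset(s): ",
         paste(subsets[infeasible], collapse = ", "), call. = FALSE)

  with_seed(seed, {
    n_universe <- sum(n_unique) - sum(n_shared[upper.tri(n_shared)])
    nt <- unique_cdr3(n_universe)
    v <- sample(trav_genes, n_universe, replace = TRUE)
    j_ <- sample(traj_genes, n_universe, replace = TRUE)
    has_np <- stats::runif(n_universe) < nonproductive_rate
    np_nt <- rep(NA_character_, n_universe)
    np_nt[has_np] <- corrupt_to_nonproductive(nt[has_np])
    np_v <- sample(trav_genes, n_universe, replace = TRUE)
    np_j <- sample(traj_genes, n_universe, replace = TRUE)

    ## allocate universe indices: one pool per unordered pair, then private
    cursor <- 0L
    take <- function(n) {
      idx <- seq.int(cursor + 1L, length.out = n)
      cursor <<- cursor + n
      idx
    }
    members <- stats::setNames(vector("list", p), subsets)
    for (s in subsets) members[[s]] <- integer(0)
    for (i in seq_len(p - 1L)) for (jj in seq.int(i + 1L, p)) {
      if (n_shared[i, jj] > 0L) {
        pool <- take(n_shared[i, jj])
        members[[i]] <- c(members[[i]], pool)
        members[[jj]] <- c(members[[jj]], pool)
      }
    }
    for (i in seq_len(p)) {
      members[[i]] <- c(members[[i]], take(n_unique[i] - committed[i]))
    }

    out <- stats::setNames(vector("list", p), subsets)
    for (s in subsets) {
      idx <- members[[s]]
      counts <- draw_counts(length(idx), "zipf", zipf_exponent[s])
      prod <- data.frame(cdr3_nt = nt[idx], cdr3_aa = translate_nt(nt[idx]),
                         v_gene = v[idx], j_gene = j_[idx],
                         templates = as.integer(counts),
                         frame = "productive", stringsAsFactors = FALSE)
      sel <- has_np[idx]
      if (any(sel)) {
        np <- data.frame(cdr3_nt = np_nt[idx][sel], cdr3_aa = NA_character_,
                         v_gene = np_v[idx][sel], j_gene = np_j[idx][sel],
                         templates = as.integer(counts[sel]),
                         frame = "nonproductive", stringsAsFactors = FALSE)
        prod <- rbind(prod, np)
      }
      out[[s]] <- repertoire(
        prod,
        label = list(donor = donor, compartment = compartment,
                     subset = s, tissue = tissue))
    }
    out
  })
}

## --- synthetic donor cohorts -------------------------------------------

subset_labels <- c("naive", "SCM", "CM", "EM", "EMRA")

## per-(tissue, compartment) mixture parameters: naive fraction at age 40,
## its per-year slope, and how the memory mass splits across SCM/CM/EM/EMRA.
## Anchored at the subset medians reported for blood, mesenteric lymph node,
## spleen and ileum, with the naive decline steeper in blood than in MLN and
## the ileum dominated by effector memory cells.
mixture_params <- list(
  blood = list(
    CD4 = list(naive0 = 0.41, slope = -0.008, w = c(0.05, 0.45, 0.35, 0.15)),
    CD8 = list(naive0 = 0.30, slope = -0.010, w = c(0.04, 0.10, 0.30, 0.56))),
  MLN = list(
    CD4 = list(naive0 = 0.45, slope = -0.004, w = c(0.06, 0.50, 0.38, 0.06)),
    CD8 = list(naive0 = 0.38, slope = -0.004, w = c(0.04, 0.15, 0.62, 0.19))),
  spleen = list(
    CD4 = list(naive0 = 0.12, slope = -0.003, w = c(0.05, 0.48, 0.40, 0.07)),
    CD8 = list(naive0 = 0.05, slope = -0.0015, w = c(0.03, 0.12, 0.60, 0.25))),
  ileum = list(
    CD4 = list(naive0 = 0.06, slope = -0.002, w = c(0.02, 0.10, 0.80, 0.08)),
    CD8 = list(naive0 = 0.04, slope = -0.0015, w = c(0.01, 0.04, 0.70, 0.25))))

#' Expected subset mixture at a given age
#'
#' The age-dependent five-subset mixture used by the cohort generator: the
#' naive fraction declines linearly with age (clamped to [0.01, 0.95]) from
#' a tissue- and compartment-specific anchor at age 40, and the remaining
#' mass is split across SCM/CM/EM/EMRA with fixed tissue-specific weights.
#' Mixtures sum to 1 at every age.
#'
#' @param age donor age in years.
#' @param tissue one of \code{"blood"}, \code{"MLN"}, \code{"spleen"},
#'   \code{"ileum"}.
#' @param compartment \code{"CD4"} or \code{"CD8"}.
#' @return named numeric vector of five probabilities summing to 1.
#' @export
subset_mixture <- function(age, tissue = "blood", compartment = "CD4") {
  par <- mixture_params[[tissue]][[compartment]]
  if (is.null(par))
    stop("no mixture defined for tissue '", tissue, "', compartment '",
         compartment, "'", call. = FALSE)
  naive <- min(max(par$naive0 + par$slope * (age - 40), 0.01), 0.95)
  mem <- (1 - naive) * par$w / sum(par$w)
  stats::setNames(c(naive, mem), subset_labels)
}

ki67_base <- c(naive = 0.01, SCM = 0.08, CM = 0.05, EM = 0.03, EMRA = 0.02)
ki67_tissue_mult <- c(blood = 1.2, MLN = 0.7, spleen = 0.7, ileum = 1.5)

cd21_naive_rate <- function(age, compartment) {
  if (compartment == "CD4") pmax(0, 0.6 * (50 - age) / 30)
  else pmax(0.05, 0.65 - 0.01 * age)
}

cd21_memory_rates <- list(
  CD4 = c(blood = 0.01, MLN = 0.05, spleen = 0.08, ileum = 0.05),
  CD8 = c(blood = 0.02, MLN = 0.10, spleen = 0.227, ileum = 0.10))

## canonical Table-style marker profiles; EM cells get heterogeneous
## CD27/CD28 (drawn Bernoulli(0.5)), CD62L mirrors CCR7
canonical_profile <- function(subset, n) {
  base <- switch(subset,
    naive = c(CD45RA = 1, CCR7 = 1, CD27 = 1, CD28 = 1, CD95 = 0),
    SCM   = c(CD45RA = 1, CCR7 = 1, CD27 = 1, CD28 = 1, CD95 = 1),
    CM    = c(CD45RA = 0, CCR7 = 1, CD27 = 1, CD28 = 1, CD95 = 0),
    EM    = c(CD45RA = 0, CCR7 = 0, CD27 = NA, CD28 = NA, CD95 = 0),
    EMRA  = c(CD45RA = 1, CCR7 = 0, CD27 = 0, CD28 = 0, CD95 = 0))
  m <- matrix(rep(base, each = n), nrow = n,
              dimnames = list(NULL, names(base)))
  for (col in c("CD27", "CD28")) {
    if (anyNA(m[, col]))
      m[, col] <- as.numeric(stats::runif(n) < 0.5)
  }
  m
}

#' Generate a synthetic donor cohort of marker-called cells
#'
#' Emulates the cohort structure the phenotyping pipeline consumes: donors
#' of random ages, each contributing one cell sample per (tissue,
#' compartment), with every cell's subset drawn from the age-dependent
#' mixture of \code{\link{subset_mixture}} (plus a donor-level logit-normal
#' perturbation of the naive fraction, giving realistic between-donor
#' scatter). Each cell's marker vector is its subset's canonical profile
#' with independent per-marker flips at \code{marker_noise}; Ki67, CD21 and
#' CD31 are set by subset-, tissue- and age-specific rates (naive-cell CD21
#' declines with age and reaches zero after age 50 in the CD4 compartment,
#' the generator's stand-in for the decline of thymic output). The true
#' generating subset is kept in column \code{true_subset} as ground truth.
#'
#' Deterministic given \code{seed}.
#'
#' @param n_donors number of donors (default 12).
#' @param age_range donor age range in years (default 20-70).
#' @param tissues subset of \code{c("blood", "MLN", "spleen", "ileum")}.
#' @param compartments subset of \code{c("CD4", "CD8")}.
#' @param cells_per_group cells per (donor, tissue, compartment) sample.
#' @param marker_noise per-marker flip probability for the classification
#'   markers (default 0.02).
#' @param donor_sd sd of the donor-level logit perturbation of the naive
#'   fraction (default 0.3).
#' @param seed integer seed.
#' @return data.frame of cells: metadata, \code{true_subset} and 0/1 marker
#'   columns.
#' @export
generate_cohort <- function(n_donors = 12L,
                            age_range = c(20, 70),
                            tissues = c("blood", "MLN", "spleen", "ileum"),
                            compartments = c("CD4", "CD8"),
                            cells_per_group = 2000L,
                            marker_noise = 0.02,
                            donor_sd = 0.3,
                            seed = 1L) {
  stopifnot(n_donors >= 1L, cells_per_group >= 1L,
            marker_noise >= 0, marker_noise <= 1)
  with_seed(seed, {
    ages <- round(stats::runif(n_donors, age_range[1], age_range[2]), 1)
    cmv <- ifelse(stats::runif(n_donors) < 0.5, "positive", "negative")
    donor_eps <- stats::rnorm(n_donors, 0, donor_sd)
    blocks <- list()
    for (d in seq_len(n_donors)) {
      for (tis in tissues) {
        for (comp in compartments) {
          mix <- subset_mixture(ages[d], tis, comp)
          ## donor-level shift of the naive fraction on the logit scale
          lg <- stats::qlogis(min(max(mix["naive"], 1e-6), 1 - 1e-6))
          naive <- stats::plogis(lg + donor_eps[d])
          mix <- c(naive, (1 - naive) * mix[-1] / sum(mix[-1]))
          subs <- sample(subset_labels, cells_per_group, replace = TRUE,
                         prob = mix)
          blocks[[length(blocks) + 1L]] <- make_cells(
            subs, donor = sprintf("D%02d", d), age = ages[d],
            tissue = tis, cmv = cmv[d], compartment = comp,
            marker_noise = marker_noise)
        }
      }
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

## build the marker table for one sample given each cell's true subset;
## caller owns the RNG state
make_cells <- function(subs, donor, age, tissue, cmv, compartment,
                       marker_noise) {
  n <- length(subs)
  m <- matrix(0, n, 5, dimnames = list(NULL, c("CD45RA", "CCR7", "CD27",
                                               "CD28", "CD95")))
  for (s in unique(subs)) {
    rows <- subs == s
    m[rows, ] <- canonical_profile(s, sum(rows))
  }
  cd62l <- m[, "CCR7"]
  if (marker_noise > 0) {
    for (col in colnames(m)) {
      flip <- stats::runif(n) < marker_noise
      m[flip, col] <- 1 - m[flip, col]
    }
    flip <- stats::runif(n) < marker_noise
    cd62l[flip] <- 1 - cd62l[flip]
  }
  naive_cell <- subs == "naive"
  ki67_rate <- unname(ki67_base[subs]) * ki67_tissue_mult[[tissue]]
  ki67 <- as.numeric(stats::runif(n) < pmin(ki67_rate, 1))
  cd21_rate <- ifelse(naive_cell, cd21_naive_rate(age, compartment),
                      cd21_memory_rates[[compartment]][[tissue]])
  cd21 <- as.numeric(stats::runif(n) < cd21_rate)
  cd31_rate <- ifelse(naive_cell,
                      if (compartment == "CD4")
                        min(max(0.95 - 0.006 * (age - 20), 0.2), 1)
                      else 0.95,
                      0.2)
  cd31 <- as.numeric(stats::runif(n) < cd31_rate)
  data.frame(
    donor_id = donor, age_years = age, tissue = tissue, cmv_status = cmv,
    compartment = compartment, true_subset = subs,
    CD45RA = m[, "CD45RA"], CCR7 = m[, "CCR7"], CD27 = m[, "CD27"],
    CD28 = m[, "CD28"], CD95 = m[, "CD95"], CD62L = cd62l,
    CD31 = cd31, CD21 = cd21, Ki67 = ki67,
    stringsAsFactors = FALSE)
}
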