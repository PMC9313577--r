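test_that("Simpson's diversity and clonality match their defining formulas", {
  expect_equal(simpson_diversity(c(7)), 1)           # monoclonal
  expect_equal(simpson_diversity(rep(1, 20)), 0)     # fully polyclonal
  expect_equal(simpson_diversity(c(2, 1, 1)), 2 / 12)
  expect_equal(simpson_clonality(c(2, 1, 1)), sqrt(1 / 6))
  expect_equal(simpson_clonality(c(9)), 1)
  expect_equal(simpson_clonality(rep(1, 50)), 0)

  expect_error(simpson_diversity(c(1)), "N < 2")
  expect_error(simpson_diversity(c(2, 0)), "positive integers")
  expect_error(simpson_diversity(numeric(0)), "positive integers")
})

test_that("diversity equals the ordered-pair enumeration oracle exactly", {
  set.seed(101)
  for (i in 1:50) {
    n_clones <- sample(2:8, 1)
    counts <- sample(1:6, n_clones, replace = TRUE)
    if (sum(counts) < 2) next
    expect_equal(simpson_diversity(counts), brute_simpson(counts),
                 tolerance = 1e-14)
  }
})

test_that("merging two clones strictly increases diversity", {
  set.seed(55)
  for (i in 1:20) {
    counts <- sample(1:10, sample(3:8, 1), replace = TRUE)
    d0 <- simpson_diversity(counts)
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    expect_gt(simpson_diversity(merged), d0)
  }
})

test_that("Jaccard index follows its set definition and is symmetric", {
  expect_equal(jaccard_index(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard_index(letters[1:3], letters[10:12]), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("b", "c", "d")),
               jaccard_index(c("b", "c", "d"), c("a", "b")))
  expect_error(jaccard_index(character(0), "a"), "empty")
  ## repertoires are accepted directly
  rep <- make_rep(c(3, 2, 1))
  expect_equal(jaccard_index(rep, rep), 1)
})

test_that("subsample_unique draws uniformly without replacement", {
  rep <- make_rep(c(5, 3, 1))
  expect_identical(subsample_unique(rep, 3), rep)  # k = R is the identity
  expect_error(subsample_unique(rep, 4), "exceeds")
  expect_error(subsample_unique(rep, 0), "positive")

  ## k = 1 from 3 clonotypes: each selected 1/3 of the time
  keys <- repertoire_keys(rep)
  picks <- withr::with_seed(77, replicate(30000, {
    repertoire_keys(subsample_unique(rep, 1))
  }))
  freq <- table(factor(picks, levels = keys)) / 30000
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  ## k = 2: template counts are retained for the drawn records
  sub <- withr::with_seed(3, subsample_unique(rep, 2))
  expect_equal(sub$R, 2L)
  expect_true(all(sub$clonotypes$templates %in% rep$clonotypes$templates))
})

test_that("resampled clonality matches the exhaustive subset expectation", {
  counts <- c(10, rep(1, 9))
  rep <- make_rep(counts)
  oracle <- exact_subsample_clonality(counts, k = 5)
  expect_equal(oracle$n_subsets, 252L)

  n_iter <- 10000L
  res <- resampled_clonality(rep, k = 5, n_iter = n_iter, seed = 19)
  mc_se <- oracle$sd / sqrt(n_iter)
  expect_lt(abs(res$resampled_mean - oracle$mean), 3 * mc_se)
})

test_that("resampled clonality at full depth reproduces the point value", {
  rep <- make_rep(c(4, 2, 1, 1))
  res <- resampled_clonality(rep, k = rep$R, n_iter = 50, seed = 1)
  expect_equal(res$resampled_mean, res$point_value)
  expect_equal(res$resampled_sd, 0)
})

test_that("resampled statistics are bit-reproducible given a seed", {
  rep <- generate_repertoire(200, seed = 8)
  a <- resampled_clonality(rep, k = 50, n_iter = 300, seed = 123)
  b <- resampled_clonality(rep, k = 50, n_iter = 300, seed = 123)
  expect_identical(a, b)
  c2 <- resampled_clonality(rep, k = 50, n_iter = 300, seed = 124)
  expect_false(identical(a$resampled_mean, c2$resampled_mean))

  repB <- generate_repertoire(150, seed = 9, label = list(subset = "other"))
  j1 <- resampled_jaccard(rep, repB, k = 100, n_iter = 200, seed = 5)
  j2 <- resampled_jaccard(rep, repB, k = 100, n_iter = 200, seed = 5)
  expect_identical(j1$jaccard_mean, j2$jaccard_mean)
})

test_that("resampled Jaccard is symmetric and matches the exhaustive oracle", {
  ## 6-vs-6 clonotypes with 3 shared keys
  shared <- make_rep(rep(1, 3), start_index = 1L)
  repA <- make_rep(rep(1, 6), start_index = 1L,
                   label = list(subset = "A"))
  repB_df <- rbind(shared$clonotypes,
                   make_rep(rep(1, 3), start_index = 100L)$clonotypes)
  repB <- repertoire(repB_df, label = list(subset = "B"))
  expect_equal(length(intersect(repertoire_keys(repA),
                                repertoire_keys(repB))), 3L)

  oracle <- exact_subsample_jaccard(repertoire_keys(repA),
                                    repertoire_keys(repB), k = 3)
  expect_equal(oracle$n_pairs, 400L)

  n_iter <- 10000L
  res <- resampled_jaccard(repA, repB, k = 3, n_iter = n_iter, seed = 31)
  mc_se <- oracle$sd / sqrt(n_iter)
  expect_lt(abs(res$jaccard_mean - oracle$mean), 3 * mc_se)
  expect_equal(res$n_shared_full, 3L)

  ## symmetry under swapping arguments (per-label RNG substreams)
  swapped <- resampled_jaccard(repB, repA, k = 3, n_iter = n_iter, seed = 31)
  expect_equal(swapped$jaccard_mean, res$jaccard_mean)

  ## identical repertoires at full depth: exactly 1 with zero spread
  full <- resampled_jaccard(repA, repA, k = 6, n_iter = 10, seed = 1)
  expect_equal(full$jaccard_mean, 1)
  expect_equal(full$jaccard_sd, 0)

  ## disjoint repertoires can never intersect
  repC <- make_rep(rep(1, 6), start_index = 500L,
                   label = list(subset = "C"))
  dis <- resampled_jaccard(repA, repC, k = 3, n_iter = 100, seed = 2)
  expect_equal(dis$jaccard_mean, 0)
})

test_that("resampling spread shrinks roughly as 1/sqrt(n_iter)", {
  rep <- generate_repertoire(40, seed = 12)
  means_at <- function(n_iter) {
    vapply(1:12, function(s) {
      resampled_clonality(rep, k = 10, n_iter = n_iter,
                          seed = 1000 + s)$resampled_mean
    }, numeric(1))
  }
  spread_small <- stats::sd(means_at(100L))
  spread_big <- stats::sd(means_at(10000L))
  ratio <- spread_small / spread_big  # ~10 in expectation
  expect_gt(ratio, 3)
  expect_lt(ratio, 30)
})

test_that("pairwise overlap matrix is symmetric with unit diagonal", {
  repA <- make_rep(rep(1, 8), start_index = 1L, label = list(subset = "A"))
  repB <- make_rep(rep(1, 8), start_index = 1L, label = list(subset = "B"))
  repC <- make_rep(rep(1, 8), start_index = 900L,
                   label = list(subset = "C"))
  ov <- pairwise_overlap_matrix(list(A = repA, B = repB, C = repC),
                                n_iter = 50, seed = 3)
  expect_equal(diag(ov$jaccard), c(A = 1, B = 1, C = 1))
  expect_equal(ov$jaccard, t(ov$jaccard))
  expect_equal(ov$jaccard["A", "B"], 1)  # identical repertoires
  expect_equal(ov$jaccard["A", "C"], 0)  # disjoint
  expect_equal(ov$k, 8L)

  ## all-nonproductive repertoire is excluded with a warning; < 2 left errors
  repD <- make_rep(rep(1, 4), frame = "nonproductive",
                   label = list(subset = "D"), start_index = 300L)
  expect_warning(
    ov2 <- pairwise_overlap_matrix(list(A = repA, C = repC, D = repD),
                                   n_iter = 20, seed = 1),
    "excluded")
  expect_equal(dim(ov2$jaccard), c(2L, 2L))
  expect_error(
    suppressWarnings(pairwise_overlap_matrix(list(A = repA, D = repD),
                                             n_iter = 20, seed = 1)),
    "at least two")
})

test_that("clonality squared equals diversity across random repertoires", {
  set.seed(202)
  for (i in 1:25) {
    counts <- sample(1:30, sample(2:12, 1), replace = TRUE)
    expect_equal(simpson_clonality(counts)^2, simpson_diversity(counts),
                 tolerance = 1e-12)
    cl <- simpson_clonality(counts)
    expect_true(cl >= 0 && cl <= 1)
  }
})
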