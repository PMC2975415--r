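random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
  d
}

test_that("complete_linkage reproduces hand agglomerations", {
  d <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- complete_linkage(d)
  expect_equal(tr$hclust$height, 0.5)
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- complete_linkage(d3)
  expect_equal(tr3$hclust$height, c(0.1, 0.9))
  expect_error(complete_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("complete_linkage matches the brute-force oracle and heights are monotone", {
  for (seed in 1:10) {
    d <- random_dist(8, seed)
    tr <- complete_linkage(d)
    expect_false(is.unsorted(tr$hclust$height))
    orc <- oracle_complete_linkage(d)
    expect_equal(tr$hclust$height, orc$heights, tolerance = 1e-12)
    for (k in seq_along(orc$heights)) {
      mem <- cutree(tr$hclust, k = 8 - k)[rownames(d)]
      expect_true(same_partition(unname(mem), orc$partitions[[k]]),
                  label = sprintf("seed %d merge %d", seed, k))
    }
  }
})

test_that("cut_tree behaves as a weakly decreasing step function of height", {
  d <- random_dist(10, 42)
  tr <- complete_linkage(d)
  expect_equal(cut_tree(tr, 0)$n_clusters, 10)
  expect_equal(cut_tree(tr, max(tr$hclust$height))$n_clusters, 1)
  hs <- seq(0, 1, by = 0.05)
  counts <- vapply(hs, function(h) cut_tree(tr, h)$n_clusters, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gain_ratio matches direct entropy arithmetic and its conventions", {
  expect_equal(as.numeric(gain_ratio(c(1, 1, 2, 2), c("P", "P", "N", "N"))), 1)
  expect_equal(as.numeric(gain_ratio(c(1, 1, 2, 2), c("P", "P", "P", "P"))), 0)
  expect_equal(as.numeric(gain_ratio(c(1, 1, 2, 2), c("P", "N", "P", "N"))), 0)
  g1 <- gain_ratio(c(1, 2, 2, 1), c("P", "N", "P", "N"))
  # single cluster: SplitInfo 0, flagged degenerate
  g <- gain_ratio(rep(1, 4), c("P", "P", "N", "N"))
  expect_equal(as.numeric(g), 0)
  expect_true(attr(g, "degenerate"))
  # invariance under P <-> N relabeling, and agreement with the oracle
  set.seed(21)
  for (i in 1:20) {
    mem <- sample(1:3, 6, TRUE)
    lab <- sample(c("P", "N"), 6, TRUE)
    flip <- ifelse(lab == "P", "N", "P")
    expect_equal(as.numeric(gain_ratio(mem, lab)),
                 as.numeric(gain_ratio(mem, flip)))
    expect_equal(as.numeric(gain_ratio(mem, lab)), oracle_gain_ratio(mem, lab))
  }
  expect_error(gain_ratio(c(1, 2), c("P", "U")), "P or N")
})

test_that("select_cut finds the pure two-pair cut and flags degenerate labelings", {
  # two tight pure pairs far apart
  d <- matrix(0.9, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1; d[3, 4] <- d[4, 3] <- 0.1
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tr <- complete_linkage(d)
  sc <- select_cut(tr, c(a = "P", b = "P", c = "N", d = "N"))
  expect_equal(sc$partition$n_clusters, 2)
  expect_equal(sc$gain_ratio, 1)
  expect_false(sc$degenerate)
  # labels opposing the geometry: only the all-singleton cut separates them
  sc2 <- select_cut(tr, c(a = "P", b = "N", c = "P", d = "N"))
  expect_equal(sc2$partition$n_clusters, 4)
  # constant labels: zero class entropy, every cut scores 0, flagged
  sc3 <- select_cut(tr, c(a = "P", b = "P", c = "P", d = "P"))
  expect_true(sc3$degenerate)
  expect_equal(sc3$partition$n_clusters, 1)
})

test_that("select_cut recovers label-pure subclasses on a motif family", {
  fam <- toy_training(seed = 1, n_proteins = 4, lysines = 6)
  pep <- peptides_from_histones(fam$histones, flank = 4, max_gap = 3)
  tr <- complete_linkage(distance_matrix(pep))
  sc <- select_cut(tr, setNames(pep$label, pep$peptide_id))
  labs <- setNames(pep$label, pep$peptide_id)
  purity <- vapply(split(names(sc$partition$membership),
                         sc$partition$membership),
                   function(ids) length(unique(labs[ids])) == 1, logical(1))
  expect_true(all(purity))
  expect_equal(sc$gain_ratio, 1)
})

test_that("permutation p-values follow the add-one convention and are reproducible", {
  fam <- toy_training(seed = 5, n_proteins = 3, lysines = 5)
  pep <- peptides_from_histones(fam$histones, flank = 4, max_gap = NULL)
  r1 <- permute_subclass_count(pep, n_perm = 19, seed = 7)
  r2 <- permute_subclass_count(pep, n_perm = 19, seed = 7)
  expect_identical(r1$null_statistics, r2$null_statistics)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value,
               (sum(r1$null_statistics <= r1$observed_statistic) + 1) / 20)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_error(permute_subclass_count(pep, n_perm = 0), "n_perm")
})

test_that("normalization test is a no-op on identical-length peptides", {
  fam <- toy_training(seed = 6, n_proteins = 3, lysines = 5)
  # no merging: all windows are full-width and identical length
  pep <- peptides_from_histones(fam$histones, flank = 4, max_gap = 3)
  expect_true(all(nchar(pep$window) == nchar(pep$window[1])))
  r <- permute_normalization(pep, n_perm = 19, seed = 3)
  expect_equal(r$observed_statistic, 0)
})

test_that("histone-association test detects aligned types and ignores shuffled ones", {
  part <- structure(list(cut_height = 0.5,
                         membership = setNames(rep(1:3, each = 4),
                                               paste0("p", 1:12)),
                         n_clusters = 3),
                    class = "subclass_partition")
  types <- setNames(rep(c("H3", "H4", "H2B"), each = 4), paste0("p", 1:12))
  r <- permute_histone_association(part, types, n_perm = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
  set.seed(2)
  ps <- vapply(1:20, function(i) {
    permute_histone_association(part, setNames(sample(types), names(types)),
                                n_perm = 39, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)  # roughly uniform under the null
})

test_that("spatial coherence on the 3-point toy matches exhaustive enumeration", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0))
  rownames(coords) <- paste0("p", 1:3)
  part <- structure(list(cut_height = 0.5,
                         membership = setNames(c(1L, 1L, 2L), paste0("p", 1:3)),
                         n_clusters = 2),
                    class = "subclass_partition")
  # exhaustive over the 3 distinct assignments: only the observed one has a
  # statistic this small, so p -> 1/3
  r <- permute_spatial_coherence(part, coords, n_perm = 2999, seed = 4)
  expect_equal(r$p_value, 1 / 3, tolerance = 0.05)
  # missing coordinates are dropped with a warning
  part4 <- structure(list(cut_height = 0.5,
                          membership = setNames(c(1L, 1L, 2L, 2L), paste0("p", 1:4)),
                          n_clusters = 2),
                     class = "subclass_partition")
  coords4 <- rbind(coords, p4 = c(51, 0, 0))
  expect_warning(
    permute_spatial_coherence(part4, coords4[1:3, , drop = FALSE],
                              n_perm = 9, seed = 1),
    "without coordinates")
})

test_that("newick serialization reflects merge heights", {
  d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- tree_to_newick(complete_linkage(d))
  expect_match(nwk, "^\\(.*\\);$")
  expect_match(nwk, "c:0.8", fixed = TRUE)
})
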