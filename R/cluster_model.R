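#' Complete-linkage subclass model
#'
#' @description
#' Peptides are clustered agglomeratively under complete (maximum) linkage,
#' whose merge heights are non-decreasing.  Cutting the dendrogram at a
#' height yields subclasses; the cut is scored by the information gain ratio
#' of the acetylation labels given the partition, and the selected cut
#' maximizes the ratio while minimizing the number of subclasses.
#' Permutation tests assess whether the subclass structure, the effect of
#' length normalization, the association with histone type, and the spatial
#' coherence of subclasses could arise by chance.
#'
#' @name cluster_model
NULL

#' Build the complete-linkage tree over a peptide distance matrix
#'
#' @param dm a `peptide_dist` object (or a symmetric matrix with dimnames).
#' @return object of class `cluster_tree`: list with the underlying
#'   `hclust` fit and the ordered leaf `ids`.
#' @export
complete_linkage <- function(dm) {
  vals <- if (inherits(dm, "peptide_dist")) dm$values else as.matrix(dm)
  if (nrow(vals) < 2L) stop("need at least 2 leaves")
  hc <- stats::hclust(stats::as.dist(vals), method = "complete")
  if (is.unsorted(hc$height)) {
    stop("internal error: complete-linkage heights not monotone")
  }
  structure(list(hclust = hc, ids = hc$labels), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %d merges, max height %.3f\n",
              length(x$ids), length(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut a cluster tree at a height
#'
#' Clusters are the connected components obtained by discarding all merges
#' above `h`.
#'
#' @param tree a `cluster_tree`.
#' @param h non-negative cut height.
#' @return object of class `subclass_partition`: list with `cut_height`,
#'   named integer `membership` and `n_clusters`.
#' @export
cut_tree <- function(tree, h) {
  stopifnot(inherits(tree, "cluster_tree"), h >= 0)
  mem <- stats::cutree(tree$hclust, h = h)
  structure(list(cut_height = h, membership = mem,
                 n_clusters = length(unique(mem))),
            class = "subclass_partition")
}

#' @export
print.subclass_partition <- function(x, ...) {
  cat(sprintf("<subclass_partition> h=%.4g, %d clusters over %d leaves\n",
              x$cut_height, x$n_clusters, length(x$membership)))
  invisible(x)
}

# Gain ratio of a membership vector given binary labels; vectorized core
# used both by the exported function and by the permutation loops.
.gain_ratio_core <- function(membership, is_p) {
  n <- length(is_p)
  h_y <- entropy2(c(sum(is_p), n - sum(is_p)))
  sizes <- tabulate(membership)
  sizes <- sizes[sizes > 0]
  p_in <- rowsum(as.numeric(is_p), membership)[, 1]
  sz <- rowsum(rep(1, n), membership)[, 1]
  cond <- sum(vapply(seq_along(sz), function(k) {
    sz[k] / n * entropy2(c(p_in[k], sz[k] - p_in[k]))
  }, numeric(1)))
  ig <- h_y - cond
  split_info <- entropy2(sz)
  if (split_info <= 0) return(c(ratio = 0, ig = ig, split_info = 0))
  c(ratio = max(0, ig) / split_info, ig = ig, split_info = split_info)
}

#' Information gain ratio of labels given a partition
#'
#' `IG / SplitInfo` with `IG = H(labels) - sum_c (|c|/n) H(labels | c)` and
#' `SplitInfo = -sum_c (|c|/n) log2(|c|/n)` (Quinlan's gain ratio).  A
#' single-cluster partition has `SplitInfo = 0` and returns 0, flagged via
#' the `degenerate` attribute.
#'
#' @param partition a `subclass_partition`, or a membership vector.
#' @param labels character vector of `"P"` / `"N"` labels, one per leaf (in
#'   leaf order of the membership).
#' @return gain ratio in \[0, 1\], with attributes `ig` and `split_info`.
#' @export
gain_ratio <- function(partition, labels) {
  mem <- if (inherits(partition, "subclass_partition")) partition$membership
         else partition
  if (length(labels) != length(mem)) stop("labels and partition differ in length")
  if (!all(labels %in% c("P", "N"))) {
    stop("labels must be P or N (coerce U upstream)")
  }
  g <- .gain_ratio_core(as.integer(factor(mem)), labels == "P")
  structure(unname(g["ratio"]), ig = unname(g["ig"]),
            split_info = unname(g["split_info"]),
            degenerate = g["split_info"] == 0)
}

# Candidate cut heights: 0, midpoints between consecutive distinct merge
# heights (avoiding evaluation exactly on a merge knot), and one candidate
# above the top merge so the single-cluster partition is representable.
.candidate_heights <- function(tree) {
  hs <- sort(unique(tree$hclust$height))
  c(0, if (length(hs) > 1) (hs[-length(hs)] + hs[-1]) / 2,
    max(hs) + max(1e-6, 0.01 * max(hs)))
}

# Gain ratio for every column of a cutree membership matrix.
.ratio_by_column <- function(mem_mat, is_p) {
  apply(mem_mat, 2, function(m) .gain_ratio_core(m, is_p)[["ratio"]])
}

#' Select the dendrogram cut by information gain ratio
#'
#' Evaluates the gain ratio at every candidate height (0 and midpoints
#' between consecutive distinct merge heights); among the heights achieving
#' the maximal ratio it returns the one with the fewest clusters, breaking
#' remaining ties toward the larger height.  When every cut scores 0 the
#' result is the coarsest candidate cut, flagged `degenerate`.
#'
#' @param tree a `cluster_tree`.
#' @param labels `"P"`/`"N"` labels named by (or ordered as) the tree leaves.
#' @return list with `height`, `partition` (a `subclass_partition`),
#'   `gain_ratio`, `degenerate` flag and the full `candidates` table.
#' @export
select_cut <- function(tree, labels) {
  labels <- .align_labels(labels, tree$ids)
  is_p <- labels == "P"
  hs <- .candidate_heights(tree)
  mem <- stats::cutree(tree$hclust, h = hs)
  if (is.null(dim(mem))) mem <- matrix(mem, ncol = 1)
  nclus <- unname(apply(mem, 2, function(m) length(unique(m))))
  ratios <- unname(.ratio_by_column(mem, is_p))
  tab <- data.frame(height = hs, n_clusters = nclus, gain_ratio = ratios)
  degenerate <- max(ratios) <= 0
  if (degenerate) {
    best <- which.min(nclus)
  } else {
    cand <- which(ratios >= max(ratios) - 1e-12)
    cand <- cand[nclus[cand] == min(nclus[cand])]
    best <- cand[which.max(hs[cand])]
  }
  part <- structure(list(cut_height = hs[best],
                         membership = stats::setNames(mem[, best], tree$ids),
                         n_clusters = nclus[best]),
                    class = "subclass_partition")
  list(height = hs[best], partition = part, gain_ratio = ratios[best],
       degenerate = degenerate, candidates = tab)
}

.align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss) > 0) stop("labels missing for leaves: ",
                               paste(utils::head(miss, 3), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels and tree leaves differ in length")
  }
  unname(labels)
}

new_permutation_result <- function(observed, null, p, seed, n_perm,
                                   statistic = "statistic") {
  structure(list(observed_statistic = observed, null_statistics = null,
                 p_value = p, seed = seed, n_permutations = n_perm,
                 statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$observed_statistic, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

# -- permutation tests -------------------------------------------------------

# Enumerate every window that can arise from merging contiguous sub-runs of
# adjacent lysines, regardless of labels, so scores can be cached once.
.candidate_windows <- function(peptides, max_gap) {
  flank <- attr(peptides, "flank")
  seqs <- attr(peptides, "sequences")
  wins <- setNames(peptides$window, peptides$peptide_id)
  for (ix in split(seq_len(nrow(peptides)), peptides$source)) {
    pp <- peptides[ix, , drop = FALSE]
    pos <- sort(vapply(pp$positions, `[`, integer(1), 1L))
    src <- pp$source[1]; seqchr <- seqs[[src]]; L <- nchar(seqchr)
    # maximal adjacency chains ignoring labels
    brk <- c(0L, which(diff(pos) > max_gap), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      chain <- pos[(brk[b] + 1L):brk[b + 1L]]
      if (length(chain) < 2L) next
      for (i in seq_len(length(chain) - 1L)) for (j in (i + 1L):length(chain)) {
        run <- chain[i:j]
        id <- paste0(src, "_K", paste(run, collapse = "+"))
        wins[id] <- substring(seqchr, max(1L, min(run) - flank),
                              min(L, max(run) + flank))
      }
    }
  }
  wins
}

# n_clusters of the selected cut for one labeled merged peptide set, using
# a precomputed distance matrix over candidate windows.
.selected_count <- function(ids, labels, Dfull) {
  D <- Dfull[ids, ids]
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  tree <- structure(list(hclust = hc, ids = ids), class = "cluster_tree")
  sc <- select_cut(tree, stats::setNames(labels, ids))
  sc$partition$n_clusters
}

#' Permutation test of the selected subclass count
#'
#' Null hypothesis: the selected number of subclasses could be as small as
#' observed when acetylation labels are assigned at random.  Labels are
#' permuted over the unmerged peptides and the full pipeline is re-run per
#' permutation -- including adjacent-lysine merging, which is
#' label-dependent -- before the gain-ratio cut is re-selected.  Small p
#' means the labels genuinely compress the tree into few subclasses.
#'
#' @param peptides an *unmerged* `lysine_peptides` data frame with `P`/`N`
#'   labels (`U` coerced to `N`).
#' @param n_perm number of permutations.
#' @param seed integer seed (results are reproducible given the seed).
#' @param max_gap adjacency threshold used for merging (default 3).
#' @param mode distance mode, `"raw"` or `"length_normalized"`.
#' @param params an [alignment_params()] list.
#' @return a `permutation_result`; p-value uses the add-one convention
#'   `(r + 1) / (n_perm + 1)` counting null counts `<=` observed.
#' @export
permute_subclass_count <- function(peptides, n_perm, seed = 1, max_gap = 3,
                                   mode = c("raw", "length_normalized"),
                                   params = alignment_params()) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- ifelse(peptides$label == "U", "N", peptides$label)
  wins <- .candidate_windows(peptides, max_gap)
  S <- .sw_score_matrix(unname(wins), params)
  Dfull <- .dist_transform(S, diag(S), nchar(wins), mode, params$transform)
  dimnames(Dfull) <- list(names(wins), names(wins))

  run_once <- function(labs) {
    pp <- peptides
    pp$label <- labs
    merged <- merge_adjacent(pp, max_gap = max_gap)
    .selected_count(merged$peptide_id, merged$label, Dfull)
  }
  observed <- run_once(labels)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    run_once(sample(labels))
  }, numeric(1)))
  p <- (sum(null <= observed) + 1) / (n_perm + 1)
  new_permutation_result(observed, null, p, seed, n_perm,
                         "selected subclass count")
}

#' Permutation test of the length-normalization effect
#'
#' Statistic: reduction in the selected subclass count when switching from
#' the raw to the length-normalized distance.  The null distribution is
#' built by shuffling the per-pair minimum-length normalization factors
#' across peptide pairs before recomputing the normalized matrix, so it
#' captures reductions achievable by arbitrary (length-unrelated)
#' rescaling.  p counts null reductions `>=` the observed one (add-one).
#'
#' @param peptides a *merged* `lysine_peptides` data frame with `P`/`N`
#'   labels (`U` coerced to `N`).
#' @inheritParams permute_subclass_count
#' @return a `permutation_result`.
#' @export
permute_normalization <- function(peptides, n_perm, seed = 1,
                                  params = alignment_params()) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(peptides) < 3L) stop("need at least 3 peptides")
  labels <- ifelse(peptides$label == "U", "N", peptides$label)
  ids <- peptides$peptide_id
  wins <- setNames(peptides$window, ids)
  len <- nchar(wins)
  S <- .sw_score_matrix(unname(wins), params)
  self <- diag(S)
  count_for <- function(D) {
    dimnames(D) <- list(ids, ids)
    .selected_count(ids, labels, D)
  }
  raw_count <- count_for(.dist_transform(S, self, len, "raw", params$transform))
  norm_count <- count_for(.dist_transform(S, self, len, "length_normalized",
                                          params$transform))
  observed <- raw_count - norm_count
  n <- length(ids)
  ut <- upper.tri(matrix(0, n, n))
  lmin0 <- outer(len, len, pmin)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lmin <- lmin0
    lmin[ut] <- sample(lmin0[ut])
    lmin[lower.tri(lmin)] <- t(lmin)[lower.tri(lmin)]
    Dp <- .dist_transform(S, self, len, "length_normalized",
                          params$transform, lmin = lmin)
    raw_count - count_for(Dp)
  }, numeric(1)))
  p <- (sum(null >= observed) + 1) / (n_perm + 1)
  new_permutation_result(observed, null, p, seed, n_perm,
                         "subclass-count reduction under normalization")
}

#' Permutation test of histone-type association with subclasses
#'
#' Statistic: information gain of the histone family given the subclass
#' partition.  The null permutes family labels over leaves; small p means
#' peptides of the same histone type co-cluster far more than chance.
#'
#' @param partition a `subclass_partition`.
#' @param histone_types character vector of family labels, named by leaf id
#'   or ordered as the partition's membership.
#' @inheritParams permute_subclass_count
#' @return a `permutation_result` (p counts null `>=` observed, add-one).
#' @export
permute_histone_association <- function(partition, histone_types, n_perm,
                                        seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  mem <- partition$membership
  types <- .align_labels(histone_types, names(mem))
  info_gain <- function(ty) {
    n <- length(ty)
    h <- entropy2(table(ty))
    cond <- sum(vapply(split(ty, mem), function(g) {
      length(g) / n * entropy2(table(g))
    }, numeric(1)))
    h - cond
  }
  observed <- info_gain(types)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    info_gain(sample(types))
  }, numeric(1)))
  p <- (sum(null >= observed) + 1) / (n_perm + 1)
  new_permutation_result(observed, null, p, seed, n_perm,
                         "information gain of histone type")
}

#' Permutation test of within-subclass spatial coherence
#'
#' Statistic: mean Euclidean distance between epsilon-N coordinates of
#' leaves sharing a subclass.  The null permutes subclass assignments over
#' leaves; small p means subclasses are spatially compact in the nucleosome.
#'
#' @param partition a `subclass_partition`.
#' @param coords numeric matrix of 3D coordinates (rows named by leaf id).
#'   Leaves without coordinates are dropped with a warning.
#' @inheritParams permute_subclass_count
#' @return a `permutation_result` (p counts null `<=` observed, add-one).
#' @export
permute_spatial_coherence <- function(partition, coords, n_perm, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  mem <- partition$membership
  have <- intersect(names(mem), rownames(coords))
  have <- have[stats::complete.cases(coords[have, , drop = FALSE])]
  dropped <- setdiff(names(mem), have)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d leaves without coordinates", length(dropped)))
  }
  if (length(have) < 3L) stop("need at least 3 leaves with coordinates")
  mem <- mem[have]
  D <- as.matrix(stats::dist(coords[have, , drop = FALSE]))
  same <- outer(mem, mem, "==") & upper.tri(D)
  if (!any(same)) stop("no within-subclass pairs among leaves with coordinates")
  stat_for <- function(m) {
    s <- outer(m, m, "==") & upper.tri(D)
    mean(D[s])
  }
  observed <- mean(D[same])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_for(sample(mem))
  }, numeric(1)))
  p <- (sum(null <= observed) + 1) / (n_perm + 1)
  new_permutation_result(observed, null, p, seed, n_perm,
                         "mean within-subclass epsilon-N distance")
}

#' Serialize a cluster tree to Newick
#'
#' Branch lengths place each merge at its linkage height (leaves at height
#' 0), so the Newick tree is an ultrametric rendering of the dendrogram.
#'
#' @param tree a `cluster_tree`.
#' @return single Newick string (terminated by `;`).
#' @export
tree_to_newick <- function(tree) {
  hc <- tree$hclust
  node_h <- c()
  render <- function(k) {
    if (k < 0) return(list(str = hc$labels[-k], h = 0))
    l <- render(hc$merge[k, 1]); r <- render(hc$merge[k, 2])
    h <- hc$height[k]
    list(str = sprintf("(%s:%g,%s:%g)", l$str, h - l$h, r$str, h - r$h), h = h)
  }
  paste0(render(nrow(hc$merge))$str, ";")
}
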