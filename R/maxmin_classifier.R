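#' Max-min subclass distance classifier
#'
#' @description
#' Label-pure subclasses of size >= 2 at the selected dendrogram cut act as
#' reference sets.  A query peptide's feature vector holds its complete
#' linkage distance to each subclass (the maximum distance over members),
#' and the decision score is
#'
#' `score = alpha * min_j D(x, s_j) - beta * min_i D(x, s_i) - I`
#'
#' where `j` ranges over un-acetylable and `i` over acetylable subclasses:
#' a query far from every negative subclass but close to a positive one
#' scores high.  Positive score predicts acetylable (`P`); ties fall to `N`.
#' A separate high-cutoff predictor assigns a label only to queries that
#' join a label-unanimous training cluster when inserted into the combined
#' tree cut at a fixed height.
#'
#' @name maxmin_classifier
NULL

#' Classifier weights
#' @param alpha,beta non-negative weights on the un-acetylable and
#'   acetylable subclass distances (not both zero).
#' @param intercept decision intercept `I`.
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(alpha = 1, beta = 1, intercept = 0) {
  if (alpha < 0 || beta < 0) stop("weights must be non-negative")
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  structure(list(alpha = alpha, beta = beta, intercept = intercept),
            class = "classifier_params")
}

#' Build reference subclasses from a cut tree
#'
#' Keeps clusters at `cut_height` that are label-pure (`P` or `N` after
#' coercing `U` to `N`) and have at least `min_size` members.
#'
#' @param tree a `cluster_tree` built over the training peptides.
#' @param peptides the training `lysine_peptides` data frame (provides
#'   windows and labels for the tree leaves).
#' @param cut_height cut height defining the subclasses.
#' @param min_size minimum members per reference subclass (default 2).
#' @return object of class `reference_subclasses`: list of subclasses
#'   (`id`, `label`, `member_ids`, `windows`) plus `cut_height` and the
#'   alignment-relevant attributes.
#' @export
build_reference <- function(tree, peptides, cut_height, min_size = 2) {
  stopifnot(inherits(tree, "cluster_tree"),
            inherits(peptides, "lysine_peptides"))
  labels <- stats::setNames(ifelse(peptides$label == "U", "N", peptides$label),
                            peptides$peptide_id)
  miss <- setdiff(tree$ids, names(labels))
  if (length(miss) > 0) stop("peptides missing for tree leaves")
  part <- cut_tree(tree, cut_height)
  wins <- stats::setNames(peptides$window, peptides$peptide_id)
  subs <- list()
  for (k in sort(unique(part$membership))) {
    members <- names(part$membership)[part$membership == k]
    labs <- unique(labels[members])
    if (length(members) >= min_size && length(labs) == 1L) {
      subs[[length(subs) + 1L]] <- list(
        id = sprintf("S%02d", k), label = labs,
        member_ids = members, windows = unname(wins[members]))
    }
  }
  if (length(subs) == 0L) {
    stop("no label-pure subclasses of size >= min_size: classifier untrainable")
  }
  structure(list(subclasses = subs, cut_height = cut_height),
            class = "reference_subclasses")
}

#' @export
print.reference_subclasses <- function(x, ...) {
  labs <- vapply(x$subclasses, `[[`, character(1), "label")
  cat(sprintf("<reference_subclasses> %d subclasses (%d P, %d N) at h=%.4g\n",
              length(labs), sum(labs == "P"), sum(labs == "N"), x$cut_height))
  invisible(x)
}

#' Complete-linkage feature vector of a query peptide
#'
#' Entry `j` is the maximum peptide distance from the query to any member of
#' subclass `j` (complete linkage of a point to a set).
#'
#' @param query a single peptide window (string) or one-row
#'   `lysine_peptides` data frame.
#' @param refs a `reference_subclasses` object.
#' @param mode distance mode, `"raw"` or `"length_normalized"`.
#' @param params an [alignment_params()] list.
#' @return named numeric vector, one distance per subclass.
#' @export
feature_vector <- function(query, refs, mode = c("raw", "length_normalized"),
                           params = alignment_params()) {
  mode <- match.arg(mode)
  if (inherits(query, "data.frame")) query <- query$window[1]
  vapply(refs$subclasses, function(s) {
    max(vapply(s$windows, function(w) .pair_distance(query, w, mode, params),
               numeric(1)))
  }, numeric(1)) |>
    stats::setNames(vapply(refs$subclasses, `[[`, character(1), "id"))
}

#' Max-min decision score of a query peptide
#'
#' @inheritParams feature_vector
#' @param cls a [classifier_params()] list.
#' @return signed score with attributes `label` (`"P"` if score > 0 else
#'   `"N"`) and `features` (the feature vector).
#' @export
decision_score <- function(query, refs, cls = classifier_params(),
                           mode = c("raw", "length_normalized"),
                           params = alignment_params()) {
  mode <- match.arg(mode)
  fv <- feature_vector(query, refs, mode, params)
  labs <- vapply(refs$subclasses, `[[`, character(1), "label")
  if (!all(c("P", "N") %in% labs)) {
    stop("reference must contain at least one subclass of each polarity")
  }
  score <- cls$alpha * min(fv[labs == "N"]) -
    cls$beta * min(fv[labs == "P"]) - cls$intercept
  structure(score, label = if (score > 0) "P" else "N", features = fv)
}

#' Fit the decision intercept on training scores
#'
#' Grid search (step 0.01 over the observed score range) for the intercept
#' minimizing the training false-negative rate; among intercepts achieving
#' that minimum, the one with maximal specificity (the largest such
#' intercept) is returned.
#'
#' @param scores numeric decision scores computed with intercept 0.
#' @param labels true `"P"`/`"N"` labels aligned with `scores`.
#' @param step grid step (default 0.01).
#' @return fitted intercept.
#' @export
fit_intercept <- function(scores, labels, step = 0.01) {
  stopifnot(length(scores) == length(labels), all(labels %in% c("P", "N")))
  grid <- seq(min(scores) - step, max(scores) + step, by = step)
  perf <- vapply(grid, function(I) {
    pred <- ifelse(scores - I > 0, "P", "N")
    tp <- sum(pred == "P" & labels == "P")
    fn <- sum(pred == "N" & labels == "P")
    tn <- sum(pred == "N" & labels == "N")
    fp <- sum(pred == "P" & labels == "N")
    c(fnr = if (tp + fn > 0) fn / (tp + fn) else 0,
      spec = if (tn + fp > 0) tn / (tn + fp) else 1)
  }, numeric(2))
  best <- which(perf["fnr", ] <= min(perf["fnr", ]) + 1e-12)
  best <- best[perf["spec", best] >= max(perf["spec", best]) - 1e-12]
  grid[max(best)]
}

#' High-cutoff tree-membership predictor
#'
#' Builds the complete-linkage tree over training plus query peptides, cuts
#' it at height `h`, and labels a query only when its cluster contains at
#' least one training peptide and all training peptides in the cluster agree
#' on the label; otherwise the query is left unpredicted (`NA`).  The
#' function also verifies that inserting the queries left the training-side
#' co-clustering at `h` unchanged, and warns when it did not (with tight
#' subclasses well below `h` and unrelated material well above it, the
#' insertion cannot rearrange the training tree; arbitrary distance
#' configurations can).
#'
#' @param queries `lysine_peptides` data frame of query peptides.
#' @param training `lysine_peptides` data frame with `P`/`N` labels (`U`
#'   coerced to `N`).
#' @param h cut height (default 0.364).
#' @param mode distance mode.
#' @param params an [alignment_params()] list.
#' @return data frame (`peptide_id`, `label`, `cluster`,
#'   `n_training_in_cluster`) with attribute `insertion_invariant`.
#' @export
predict_high_cutoff <- function(queries, training, h = 0.364,
                                mode = c("raw", "length_normalized"),
                                params = alignment_params()) {
  mode <- match.arg(mode)
  tr_lab <- stats::setNames(ifelse(training$label == "U", "N", training$label),
                            training$peptide_id)
  all_win <- c(stats::setNames(training$window, training$peptide_id),
               stats::setNames(queries$window, queries$peptide_id))
  if (anyDuplicated(names(all_win))) stop("duplicate peptide ids across sets")
  dm <- distance_matrix(all_win, mode = mode, params = params)
  part <- cut_tree(complete_linkage(dm), h)
  mem <- part$membership
  # insertion-invariance check on the training side
  tr_dm <- structure(list(ids = training$peptide_id,
                          values = dm$values[training$peptide_id,
                                             training$peptide_id],
                          mode = mode, params = params),
                     class = "peptide_dist")
  tr_mem <- cut_tree(complete_linkage(tr_dm), h)$membership
  comb_tr <- mem[training$peptide_id]
  invariant <- all((outer(tr_mem, tr_mem, "==") ==
                      outer(comb_tr, comb_tr, "==")))
  if (!invariant) {
    warning("query insertion changed training-side co-clustering at the cutoff")
  }
  res <- data.frame(peptide_id = queries$peptide_id,
                    label = NA_character_,
                    cluster = unname(mem[queries$peptide_id]),
                    n_training_in_cluster = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    tr_in <- names(tr_lab)[mem[names(tr_lab)] == res$cluster[i]]
    res$n_training_in_cluster[i] <- length(tr_in)
    if (length(tr_in) > 0) {
      labs <- unique(tr_lab[tr_in])
      if (length(labs) == 1L) res$label[i] <- labs
    }
  }
  attr(res, "insertion_invariant") <- invariant
  res
}

#' Confusion counts and rates of a prediction
#'
#' Standard definitions with `P` as the positive class: sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, false negative rate `fn/(fn+tp)`
#' and false positive rate `fp/(fp+tn)`.  In `semi_supervised` mode the
#' negative labels are only provisional (non-observed), so specificity and
#' the false positive rate are flagged unreliable and only the
#' false-negative-derived quantities should be quoted; `U`-labeled truths
#' are excluded from the counts.
#'
#' @param predictions named character vector of predicted `"P"`/`"N"`.
#' @param truth named character vector of true labels (`"P"`, `"N"`, `"U"`).
#' @param mode `"full"` or `"semi_supervised"`.
#' @return object of class `evaluation_report`.
#' @export
evaluate <- function(predictions, truth, mode = c("full", "semi_supervised")) {
  mode <- match.arg(mode)
  if (is.null(names(predictions)) || is.null(names(truth))) {
    stop("predictions and truth must be named")
  }
  if (!setequal(names(predictions), names(truth))) {
    stop("prediction and truth ids do not match")
  }
  truth <- truth[names(predictions)]
  keep <- truth %in% c("P", "N") & !is.na(predictions)
  pred <- predictions[keep]; tr <- truth[keep]
  tp <- sum(pred == "P" & tr == "P"); fn <- sum(pred == "N" & tr == "P")
  tn <- sum(pred == "N" & tr == "N"); fp <- sum(pred == "P" & tr == "N")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_evaluated = sum(keep), n_excluded = sum(!keep),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    false_negative_rate = rate(fn, fn + tp),
    false_positive_rate = rate(fp, fp + tn),
    mode = mode,
    reliable = if (mode == "semi_supervised")
      c("sensitivity", "false_negative_rate")
    else c("sensitivity", "specificity", "false_negative_rate",
           "false_positive_rate")),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mode=%s  tp=%d fp=%d tn=%d fn=%d\n",
              x$mode, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity=%.4g specificity=%.4g fnr=%.4g fpr=%.4g\n",
              x$sensitivity, x$specificity, x$false_negative_rate,
              x$false_positive_rate))
  if (x$mode == "semi_supervised") {
    cat("  (semi-supervised: only sensitivity / FNR are reliable)\n")
  }
  invisible(x)
}

#' Rank-sum association of accessible-surface-area features with labels
#'
#' For each ASA feature column, a two-sided Wilcoxon rank-sum test of the
#' acetylable (`P`) against non-acetylable (`N`) residues.  Features with
#' fewer than 2 observations in either group are skipped with a warning.
#'
#' @param asa_table data frame keyed by `id`, `position` with numeric ASA
#'   feature columns (e.g. `percent`, `residue`, `sidechain`, `atom`).
#' @param labels data frame with `id`, `position`, `label` columns.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return data frame: `feature`, `n_p`, `n_n`, `statistic`, `p_value`,
#'   `significant`.
#' @export
asa_association <- function(asa_table, labels, alpha = 0.05) {
  stopifnot(all(c("id", "position") %in% names(asa_table)),
            all(c("id", "position", "label") %in% names(labels)))
  key <- function(d) paste(d$id, d$position)
  lab <- stats::setNames(labels$label, key(labels))[key(asa_table)]
  feats <- setdiff(names(asa_table), c("id", "position"))
  feats <- feats[vapply(asa_table[feats], is.numeric, logical(1))]
  rows <- lapply(feats, function(f) {
    x <- asa_table[[f]][lab == "P" & !is.na(lab)]
    y <- asa_table[[f]][lab == "N" & !is.na(lab)]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("feature '%s' skipped: fewer than 2 observations in a group", f))
      return(NULL)
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    data.frame(feature = f, n_p = length(x), n_n = length(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               significant = wt$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
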