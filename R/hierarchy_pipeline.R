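#' Three-level hierarchical prediction pipeline
#'
#' @description
#' Orchestrates the full predictor.  Level 1 labels only the query peptides
#' that fall into a label-unanimous training cluster when the combined tree
#' is cut at the high cutoff.  Level 2 scores the remaining queries with
#' the max-min subclass classifier.  Level 3 re-decides the level-2
#' *positives* that map onto the structure, replacing the peptide verdict
#' with the spatial one; level-2 negatives and unmapped sites keep their
#' peptide label, and level-1 decisions are final.
#'
#' @name hierarchy_pipeline
NULL

#' Pipeline configuration
#'
#' @param flank flanking-window half-width in residues (default 12).
#' @param max_gap adjacency threshold for merging lysines (default 3).
#' @param mode peptide distance mode, `"raw"` or `"length_normalized"`.
#' @param transform score-to-distance transform (see
#'   [alignment_params()]).
#' @param gap_open,gap_extend Smith-Waterman gap penalties.
#' @param high_cutoff level-1 cut height (default 0.364).
#' @param alpha,beta,intercept max-min decision weights.
#' @param fit_intercept refit the intercept on training scores
#'   (default `FALSE`).
#' @param reference_cut cut height defining the reference subclasses;
#'   `NULL` selects it by information gain ratio.
#' @param min_subclass_size minimum members per reference subclass.
#' @param structure_path optional PDB file enabling level 3.
#' @param catalog_spec region catalog table
#'   ([default_catalog_spec()] by default).
#' @param min_match flank used when mapping sites onto structure chains.
#' @param n_surface_samples ellipsoid surface samples per distance.
#' @param adjust_negatives also re-decide level-2 negatives spatially
#'   (default `FALSE`: only positives are adjusted).
#' @param expand_merged report one output row per lysine rather than per
#'   merged peptide (default `TRUE`).
#' @param seed integer seed for the deterministic surface lattice.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(flank = 12, max_gap = 3,
                            mode = c("raw", "length_normalized"),
                            transform = c("min_self", "geometric_mean_self"),
                            gap_open = 10, gap_extend = 0.5,
                            high_cutoff = 0.364,
                            alpha = 1, beta = 1, intercept = 0,
                            fit_intercept = FALSE,
                            reference_cut = NULL, min_subclass_size = 2,
                            structure_path = NULL,
                            catalog_spec = default_catalog_spec(),
                            min_match = 8,
                            n_surface_samples = 2048,
                            adjust_negatives = FALSE,
                            expand_merged = TRUE, seed = 1) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (high_cutoff < 0) stop("high_cutoff must be >= 0")
  structure(list(flank = flank, max_gap = max_gap, mode = mode,
                 transform = transform, gap_open = gap_open,
                 gap_extend = gap_extend, high_cutoff = high_cutoff,
                 alpha = alpha, beta = beta, intercept = intercept,
                 fit_intercept = fit_intercept,
                 reference_cut = reference_cut,
                 min_subclass_size = min_subclass_size,
                 structure_path = structure_path,
                 catalog_spec = catalog_spec, min_match = min_match,
                 n_surface_samples = n_surface_samples,
                 adjust_negatives = adjust_negatives,
                 expand_merged = expand_merged, seed = seed),
            class = "pipeline_config")
}

#' Extract and merge peptides from a set of histones
#'
#' @param histones list of `histone_protein` objects.
#' @param flank flanking-window half-width.
#' @param max_gap adjacency threshold; `NULL` skips merging.
#' @param coerce_unknown coerce `U` labels to `N`.
#' @return a `lysine_peptides` data frame.
#' @export
peptides_from_histones <- function(histones, flank = 12, max_gap = 3,
                                   coerce_unknown = FALSE) {
  pep <- rbind_peptides(lapply(histones, extract_peptides, flank = flank))
  if (coerce_unknown) pep$label[pep$label == "U"] <- "N"
  if (!is.null(max_gap)) pep <- merge_adjacent(pep, max_gap = max_gap)
  pep
}

#' Run the three-level hierarchical prediction
#'
#' @param training list of `histone_protein` objects with `P`/`N` labels
#'   (unobserved lysines are treated as provisional negatives).
#' @param queries list of `histone_protein` objects to predict.
#' @param config a [pipeline_config()].
#' @return data frame of class `prediction_records`: `id`, `positions`
#'   (comma-joined), `label`, `decision_level`, `peptide_score`,
#'   `spatial_score`, `notes`; one row per lysine when
#'   `config$expand_merged`, else per merged peptide.  The configuration
#'   and run details are attached as attributes.
#' @export
run_pipeline <- function(training, queries, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(queries) == 0) stop("no query histones")
  params <- alignment_params(config$gap_open, config$gap_extend,
                             transform = config$transform)
  tr <- peptides_from_histones(training, config$flank, config$max_gap,
                               coerce_unknown = TRUE)
  if (!all(c("P", "N") %in% tr$label)) {
    stop("training data must contain both P and N labels")
  }
  qu <- peptides_from_histones(queries, config$flank, config$max_gap)

  # level 1: membership in label-unanimous training clusters at the cutoff
  lvl1 <- predict_high_cutoff(qu, tr, h = config$high_cutoff,
                              mode = config$mode, params = params)

  # reference subclasses on the training tree
  tr_dm <- distance_matrix(tr, mode = config$mode, params = params)
  tr_tree <- complete_linkage(tr_dm)
  cut_h <- config$reference_cut
  if (is.null(cut_h)) {
    cut_h <- select_cut(tr_tree, stats::setNames(tr$label, tr$peptide_id))$height
  }
  refs <- build_reference(tr_tree, tr, cut_h,
                          min_size = config$min_subclass_size)
  cls <- classifier_params(config$alpha, config$beta, config$intercept)
  if (config$fit_intercept) {
    tr_scores <- vapply(tr$window, function(w) {
      as.numeric(decision_score(w, refs, classifier_params(
        config$alpha, config$beta, 0), mode = config$mode, params = params))
    }, numeric(1))
    cls <- classifier_params(config$alpha, config$beta,
                             fit_intercept(tr_scores, tr$label))
  }

  # optional structure support for level 3
  mapping <- NULL; catalog <- NULL
  structure_ok <- !is.null(config$structure_path)
  if (structure_ok) {
    mapping <- map_sites_to_structure(c(training, queries),
                                      config$structure_path,
                                      min_match = config$min_match)
    catalog <- build_region_catalog(mapping, config$catalog_spec)
  }

  recs <- data.frame(id = qu$source,
                     positions = vapply(qu$positions, paste, character(1),
                                        collapse = ","),
                     label = lvl1$label,
                     decision_level = ifelse(is.na(lvl1$label), NA_integer_, 1L),
                     peptide_score = NA_real_, spatial_score = NA_real_,
                     notes = ifelse(is.na(lvl1$label), "",
                                    "high-cutoff tree membership"),
                     stringsAsFactors = FALSE)

  for (i in which(is.na(recs$decision_level))) {
    ds <- decision_score(qu$window[i], refs, cls, mode = config$mode,
                         params = params)
    recs$label[i] <- attr(ds, "label")
    recs$peptide_score[i] <- as.numeric(ds)
    recs$decision_level[i] <- 2L
    recs$notes[i] <- "max-min peptide score"
    adjust <- recs$label[i] == "P" || config$adjust_negatives
    if (structure_ok && adjust) {
      pos <- qu$positions[[i]]
      sel <- mapping$status == "mapped" & mapping$id == qu$source[i] &
        mapping$position %in% pos
      if (any(sel)) {
        sd <- spatial_decision(mapping[sel, c("x", "y", "z")], catalog, cls,
                               n_surface_samples = config$n_surface_samples,
                               seed = config$seed)
        recs$spatial_score[i] <- sd$score
        recs$decision_level[i] <- 3L
        recs$notes[i] <- sprintf("spatial adjustment of level-2 %s",
                                 recs$label[i])
        recs$label[i] <- sd$label
      } else {
        recs$notes[i] <- paste(recs$notes[i], "(no-structure)")
      }
    } else if (!structure_ok && recs$label[i] == "P") {
      recs$notes[i] <- paste(recs$notes[i], "(no-structure)")
    }
  }

  if (config$expand_merged) {
    idx <- rep(seq_len(nrow(recs)),
               vapply(qu$positions, length, integer(1)))
    recs <- recs[idx, , drop = FALSE]
    recs$positions <- as.character(unlist(qu$positions))
    rownames(recs) <- NULL
  }
  attr(recs, "config") <- config
  attr(recs, "reference_cut") <- cut_h
  attr(recs, "intercept") <- cls$intercept
  attr(recs, "insertion_invariant") <- attr(lvl1, "insertion_invariant")
  class(recs) <- c("prediction_records", "data.frame")
  recs
}

#' Evaluate pipeline predictions against known labels
#'
#' @param records a `prediction_records` data frame (expanded per lysine).
#' @param truth data frame `id`, `position`, `label` (`P`/`N`/`U`; `U` is
#'   not evaluable).
#' @param mode `"semi_supervised"` (default; only sensitivity / FNR
#'   reliable) or `"full"`.
#' @return an `evaluation_report` with an additional `by_level` breakdown.
#' @export
evaluate_pipeline <- function(records, truth,
                              mode = c("semi_supervised", "full")) {
  mode <- match.arg(mode)
  key <- paste(records$id, records$positions)
  if (anyDuplicated(key)) stop("records must be expanded to one row per lysine")
  pred <- stats::setNames(records$label, key)
  tr <- stats::setNames(truth$label, paste(truth$id, truth$position))
  common <- intersect(names(pred), names(tr))
  if (length(common) == 0) stop("no overlap between records and truth ids")
  rep_all <- evaluate(pred[common], tr[common], mode = mode)
  lv <- stats::setNames(records$decision_level, key)[common]
  rep_all$by_level <- lapply(split(common, lv), function(ids) {
    evaluate(pred[ids], tr[ids], mode = mode)
  })
  rep_all
}

#' Fraction of lysines predicted acetylable
#' @param records a `prediction_records` data frame.
#' @return fraction of rows labeled `P`.
#' @export
fraction_acetylable <- function(records) {
  mean(records$label == "P", na.rm = TRUE)
}

#' Write prediction records as tab-separated text
#' @param records a `prediction_records` data frame.
#' @param path output path.
#' @export
write_predictions <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
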