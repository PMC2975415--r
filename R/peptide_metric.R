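#' Peptide alignment scores and bounded distances
#'
#' @description
#' Pairwise peptide similarity is the Smith-Waterman local alignment score
#' under BLOSUM62 (gap open 10, gap extend 0.5 by default).  Scores are
#' mapped to bounded distances in \[0, 1\]:
#'
#' * raw: `d = 1 - S(a,b) / min(S(a,a), S(b,b))`
#' * length-normalized: cross- and self-scores are first divided by peptide
#'   length (`S(a,b)` by the shorter of the two lengths), then the same
#'   transform is applied.
#'
#' Identical peptides map to 0 and unrelated peptides (cross-score 0) to 1.
#' An alternative `geometric_mean_self` transform divides by
#' `sqrt(S(a,a) * S(b,b))` instead of the minimum self-score; both are
#' selectable because cut heights of the downstream dendrogram depend on
#' this choice.
#'
#' @name peptide_metric
NULL

.blosum_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$B62 <- e$BLOSUM62
  }
  .blosum_env$B62
}

#' Alignment and distance-transform parameters
#'
#' @param gap_open non-negative gap opening penalty (default 10).
#' @param gap_extend non-negative gap extension penalty (default 0.5); must
#'   not exceed `gap_open`.
#' @param matrix substitution matrix (named square matrix); default
#'   BLOSUM62.
#' @param transform score-to-distance transform: `"min_self"` (divide the
#'   cross-score by the smaller self-score) or `"geometric_mean_self"`.
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(gap_open = 10, gap_extend = 0.5, matrix = NULL,
                             transform = c("min_self", "geometric_mean_self")) {
  transform <- match.arg(transform)
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (is.null(matrix)) matrix <- .blosum62()
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix, transform = transform),
            class = "alignment_params")
}

.check_residues <- function(x, params) {
  known <- rownames(params$matrix)
  bad <- setdiff(unique(unlist(strsplit(x, ""))), known)
  if (length(bad) > 0) {
    stop(sprintf("residue(s) without substitution-matrix entry: %s",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of `a` against `b`; 0 when no positively
#' scoring local alignment exists.  `a` may be a vector, in which case one
#' score per element is returned.
#'
#' @param a character vector of peptides.
#' @param b single peptide.
#' @param params an [alignment_params()] list.
#' @return non-negative numeric score(s).
#' @export
sw_score <- function(a, b, params = alignment_params()) {
  if (any(!nzchar(a)) || !nzchar(b)) stop("peptides must be non-empty")
  .check_residues(c(a, b), params)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), b, type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE))
}

# Cross-score matrix over one window set (symmetric, includes diagonal).
.sw_score_matrix <- function(windows, params) {
  n <- length(windows)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    S[i, i:n] <- sw_score(windows[i:n], windows[i], params)
  }
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

# Core score-to-distance transform shared by the pairwise functions, the
# distance matrix and the normalization permutation test.  `S` is the
# symmetric cross-score matrix, `self` its diagonal, `len` the window
# lengths; `lmin` may override the pairwise minimum-length matrix when the
# normalization factors are deliberately shuffled.
.dist_transform <- function(S, self, len, mode, transform, lmin = NULL) {
  if (any(self <= 0)) stop("peptide with non-positive self-alignment score")
  if (mode == "length_normalized") {
    if (is.null(lmin)) lmin <- outer(len, len, pmin)
    S <- S / lmin
    self <- self / len
  }
  denom <- switch(transform,
    min_self = outer(self, self, pmin),
    geometric_mean_self = sqrt(outer(self, self)))
  D <- clip01(1 - S / denom)
  diag(D) <- 0
  (D + t(D)) / 2
}

.pair_distance <- function(a, b, mode, params) {
  S <- .sw_score_matrix(c(a, b), params)
  .dist_transform(S, diag(S), nchar(c(a, b)), mode, params$transform)[1, 2]
}

#' Raw peptide distance
#'
#' `1 - S(a,b) / min(S(a,a), S(b,b))`, clipped to \[0, 1\].
#'
#' @inheritParams sw_score
#' @param b single peptide.
#' @return distance in \[0, 1\].
#' @export
raw_distance <- function(a, b, params = alignment_params()) {
  .pair_distance(a, b, "raw", params)
}

#' Length-normalized peptide distance
#'
#' The cross-score is divided by the shorter peptide length and each
#' self-score by its own length before the raw transform, removing the
#' advantage long peptides gain from longer positive-scoring alignments.
#'
#' @inheritParams raw_distance
#' @return distance in \[0, 1\].
#' @export
normalized_distance <- function(a, b, params = alignment_params()) {
  .pair_distance(a, b, "length_normalized", params)
}

#' Full pairwise distance matrix over a peptide set
#'
#' @param peptides a `lysine_peptides` data frame, or a named character
#'   vector of windows.
#' @param mode `"raw"` or `"length_normalized"`.
#' @param params an [alignment_params()] list.
#' @return object of class `peptide_dist`: list with `ids`, symmetric
#'   `values` matrix (zero diagonal), `mode` and `params`.
#' @export
distance_matrix <- function(peptides, mode = c("raw", "length_normalized"),
                            params = alignment_params()) {
  mode <- match.arg(mode)
  if (inherits(peptides, "lysine_peptides")) {
    windows <- setNames(peptides$window, peptides$peptide_id)
  } else {
    windows <- peptides
    if (is.null(names(windows))) names(windows) <- paste0("pep", seq_along(windows))
  }
  if (length(windows) < 2L) stop("need at least 2 peptides")
  if (anyDuplicated(names(windows))) stop("duplicate peptide ids")
  S <- .sw_score_matrix(unname(windows), params)
  D <- .dist_transform(S, diag(S), nchar(windows), mode, params$transform)
  dimnames(D) <- list(names(windows), names(windows))
  structure(list(ids = names(windows), values = D, mode = mode,
                 params = params),
            class = "peptide_dist")
}

#' @export
as.dist.peptide_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' @export
print.peptide_dist <- function(x, ...) {
  cat(sprintf("<peptide_dist> %d peptides, mode=%s, transform=%s\n",
              length(x$ids), x$mode, x$params$transform))
  invisible(x)
}

#' Write a distance matrix as tab-separated long format
#' @param dm a `peptide_dist` object.
#' @param path output path.
#' @param digits decimals retained at output (default 6).
#' @export
write_distance_matrix <- function(dm, path, digits = 6) {
  n <- length(dm$ids)
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  df <- data.frame(id_a = dm$ids[idx[, 1]], id_b = dm$ids[idx[, 2]],
                   distance = round(dm$values[idx], digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
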