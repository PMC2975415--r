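#' Histone sequences, site annotations and lysine flanking peptides
#'
#' @description
#' Input/output layer of the predictor.  Histones are read from FASTA plus a
#' tab-separated per-lysine annotation table (`id`, `position`, `label` with
#' labels `P` = acetylable, `N` = not observed acetylable, `U` = unknown).
#' Flanking-window peptides are extracted around every lysine, and adjacent
#' same-label lysines are merged into a single peptide, the unit of all
#' downstream clustering and classification.
#'
#' Residue numbering is 1-based on the mature protein: by default a leading
#' initiator methionine is stripped from each FASTA sequence so positions
#' follow histone nomenclature (H3K4 is the 4th mature residue).
#'
#' @name histone_io
NULL

.VALID_AA <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Construct a histone protein record
#'
#' Validates the sequence alphabet and the per-lysine labels: every labeled
#' position must be a lysine within the sequence and labels are `P`
#' (acetylable), `N` (not observed acetylable) or `U` (unknown).
#'
#' @param id accession string.
#' @param sequence amino-acid string (mature protein).
#' @param species,family,variant optional identity strings.
#' @param labels named character vector mapping 1-based lysine positions to
#'   labels.
#' @return object of class `histone_protein`.
#' @export
new_histone_protein <- function(id, sequence, species = NA_character_,
                                family = NA_character_, variant = NA_character_,
                                labels = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  resid <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(resid), .VALID_AA)
  if (length(bad) > 0) {
    stop(sprintf("protein '%s' contains non-standard residues: %s",
                 id, paste(bad, collapse = ", ")))
  }
  if (length(labels) > 0) {
    pos <- as.integer(names(labels))
    if (anyNA(pos) || any(pos < 1L) || any(pos > nchar(sequence))) {
      stop(sprintf("protein '%s': annotation positions outside [1, %d]",
                   id, nchar(sequence)))
    }
    notk <- pos[resid[pos] != "K"]
    if (length(notk) > 0) {
      stop(sprintf("protein '%s': annotated position %d is residue '%s', not K",
                   id, notk[1], resid[notk[1]]))
    }
    if (!all(labels %in% c("P", "N", "U"))) {
      stop(sprintf("protein '%s': labels must be P, N or U", id))
    }
    labels <- labels[order(pos)]
  }
  structure(list(id = id, species = species, family = family,
                 variant = variant, sequence = sequence, labels = labels),
            class = "histone_protein")
}

#' @export
print.histone_protein <- function(x, ...) {
  cat(sprintf("<histone_protein> %s (%s %s %s), %d aa, %d annotated lysines\n",
              x$id, x$species, x$family, x$variant, nchar(x$sequence),
              length(x$labels)))
  invisible(x)
}

#' Positions of all lysines in a protein
#' @param protein a `histone_protein`.
#' @return integer vector of 1-based lysine positions.
#' @export
lysine_positions <- function(protein) {
  which(strsplit(protein$sequence, "")[[1]] == "K")
}

#' Read histone proteins and their acetylation annotations
#'
#' Parses a FASTA file and a tab-separated annotation table with header
#' `id`, `position`, `label` and attaches per-lysine labels to each
#' sequence.  FASTA headers may carry `species=`, `family=` and `variant=`
#' key-value tags after the identifier.
#'
#' @param fasta_path path to a FASTA file of histone sequences.
#' @param annotation_path path to the annotation table.
#' @param filter `"strict"` keeps only proteins with at least one `P`
#'   (experimentally acetylated) site, `"annotated"` keeps proteins with any
#'   annotation row, `"all"` keeps every FASTA entry.
#' @param mature_numbering strip a leading initiator methionine so positions
#'   follow mature histone numbering (default `TRUE`).
#' @param coerce_unknown treat `U` (unobserved) labels as `N`, reproducing a
#'   semi-supervised labeling in which every non-observed lysine is a
#'   provisional negative.
#' @return list of [histone_protein][histone_io] objects.
#' @export
read_histones <- function(fasta_path, annotation_path,
                          filter = c("strict", "annotated", "all"),
                          mature_numbering = TRUE, coerce_unknown = FALSE) {
  filter <- match.arg(filter)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("id", "position", "label") %in% names(ann))) {
    stop("annotation table must have columns id, position, label")
  }
  if (anyDuplicated(ann[c("id", "position")])) {
    d <- ann[duplicated(ann[c("id", "position")]), ]
    stop(sprintf("duplicate annotation row for id '%s' position %d",
                 d$id[1], d$position[1]))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  tag <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=(\\S+)"), h))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  unknown <- setdiff(ann$id, ids)
  if (length(unknown) > 0) {
    stop(sprintf("annotation ids not present in FASTA: %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (mature_numbering && startsWith(s, "M")) s <- substring(s, 2)
    rows <- ann[ann$id == ids[i], , drop = FALSE]
    labels <- setNames(as.character(rows$label), rows$position)
    if (coerce_unknown) labels[labels == "U"] <- "N"
    new_histone_protein(ids[i], s,
                        species = tag(headers[i], "species"),
                        family = tag(headers[i], "family"),
                        variant = tag(headers[i], "variant"),
                        labels = labels)
  })
  names(out) <- ids
  keep <- switch(filter,
    all = rep(TRUE, length(out)),
    annotated = vapply(out, function(p) length(p$labels) > 0, logical(1)),
    strict = vapply(out, function(p) any(p$labels == "P"), logical(1)))
  out[keep]
}

#' Extract flanking-window peptides around every lysine
#'
#' One peptide per lysine, using a window of at most `flank` residues on each
#' side, truncated at the sequence termini.  Unannotated lysines receive
#' label `U`.
#'
#' @param protein a `histone_protein`.
#' @param flank maximum number of flanking residues on each side
#'   (default 12).
#' @return data frame of class `lysine_peptides` with columns `peptide_id`,
#'   `source`, `positions` (list column), `window`, `label`, `span_start`,
#'   `span_end`; attributes `flank` and `sequences` carry what adjacent-run
#'   merging needs.
#' @export
extract_peptides <- function(protein, flank = 12) {
  stopifnot(inherits(protein, "histone_protein"))
  if (!is.numeric(flank) || flank < 1) stop("`flank` must be a positive integer")
  flank <- as.integer(flank)
  L <- nchar(protein$sequence)
  pos <- lysine_positions(protein)
  lab <- vapply(as.character(pos), function(p) {
    if (p %in% names(protein$labels)) unname(protein$labels[p]) else "U"
  }, character(1))
  start <- pmax(1L, pos - flank)
  end <- pmin(L, pos + flank)
  out <- data.frame(
    peptide_id = paste0(protein$id, "_K", pos),
    source = protein$id,
    window = substring(protein$sequence, start, end),
    label = lab,
    span_start = start,
    span_end = end,
    stringsAsFactors = FALSE)
  out$positions <- as.list(pos)
  out <- out[c("peptide_id", "source", "positions", "window", "label",
               "span_start", "span_end")]
  attr(out, "flank") <- flank
  attr(out, "sequences") <- setNames(protein$sequence, protein$id)
  class(out) <- c("lysine_peptides", "data.frame")
  out
}

#' Combine peptide tables from several proteins
#' @param ... `lysine_peptides` data frames.
#' @return a combined `lysine_peptides` data frame.
#' @export
rbind_peptides <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  flanks <- unique(vapply(parts, function(p) attr(p, "flank"), integer(1)))
  if (length(flanks) != 1L) stop("peptide tables use different flank sizes")
  seqs <- do.call(c, unname(lapply(parts, attr, "sequences")))
  seqs <- seqs[!duplicated(names(seqs))]
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  rownames(out) <- NULL
  attr(out, "flank") <- flanks
  attr(out, "sequences") <- seqs
  class(out) <- c("lysine_peptides", "data.frame")
  out
}

#' Merge peptides of adjacent same-label lysines
#'
#' Maximal runs of lysines whose successive positions differ by at most
#' `max_gap` *and* which carry an identical label collapse into one peptide
#' whose window spans `flank` residues left of the first lysine through
#' `flank` residues right of the last.  Runs with discordant labels are left
#' unmerged, so every merged peptide is label-pure by construction.
#'
#' @param peptides a `lysine_peptides` data frame (one or more source
#'   proteins; merging is per protein).
#' @param max_gap maximum position difference defining adjacency
#'   (default 3).
#' @return a `lysine_peptides` data frame with merged rows.
#' @export
merge_adjacent <- function(peptides, max_gap = 3) {
  stopifnot(inherits(peptides, "lysine_peptides"))
  if (!is.numeric(max_gap) || max_gap < 1) stop("`max_gap` must be positive")
  flank <- attr(peptides, "flank")
  seqs <- attr(peptides, "sequences")
  pieces <- lapply(split(seq_len(nrow(peptides)), peptides$source), function(ix) {
    pp <- peptides[ix, , drop = FALSE]
    first <- vapply(pp$positions, min, integer(1))
    pp <- pp[order(first), , drop = FALSE]
    runs <- .label_runs(vapply(pp$positions, min, integer(1)),
                        vapply(pp$positions, max, integer(1)),
                        pp$label, max_gap)
    src <- pp$source[1]
    seqchr <- seqs[[src]]
    L <- nchar(seqchr)
    do.call(rbind, lapply(runs, function(r) {
      allpos <- sort(unlist(pp$positions[r]))
      start <- max(1L, min(allpos) - flank)
      end <- min(L, max(allpos) + flank)
      data.frame(
        peptide_id = paste0(src, "_K", paste(allpos, collapse = "+")),
        source = src,
        positions = I(list(allpos)),
        window = substring(seqchr, start, end),
        label = pp$label[r[1]],
        span_start = start,
        span_end = end,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "flank") <- flank
  attr(out, "sequences") <- seqs
  class(out) <- c("lysine_peptides", "data.frame")
  out
}

# Greedy left-to-right run construction over sorted peptides: extend the
# current run while the gap from the previous peptide's last lysine to the
# next peptide's first lysine is <= max_gap and the label matches (so the
# operation is idempotent on already-merged output).
.label_runs <- function(first, last, labels, max_gap) {
  runs <- list()
  cur <- 1L
  if (length(first) == 0L) return(runs)
  for (i in seq_along(first)[-1]) {
    if (first[i] - last[i - 1L] <= max_gap && labels[i] == labels[cur[1]]) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs
}

#' Count adjacent lysine pairs and their label concordance
#'
#' @param peptides an unmerged `lysine_peptides` data frame.
#' @param max_gap adjacency threshold (default 3).
#' @return list with `n_pairs`, `n_concordant` and `concordance` (fraction of
#'   adjacent pairs whose lysines share a label; `NaN` when no pairs).
#' @export
count_adjacent_pairs <- function(peptides, max_gap = 3) {
  stopifnot(inherits(peptides, "lysine_peptides"))
  tot <- 0L; conc <- 0L
  for (ix in split(seq_len(nrow(peptides)), peptides$source)) {
    pp <- peptides[ix, , drop = FALSE]
    pos <- vapply(pp$positions, `[`, integer(1), 1L)
    o <- order(pos); pos <- pos[o]; lab <- pp$label[o]
    if (length(pos) < 2L) next
    adj <- diff(pos) <= max_gap
    tot <- tot + sum(adj)
    conc <- conc + sum(adj & lab[-length(lab)] == lab[-1])
  }
  list(n_pairs = tot, n_concordant = conc, concordance = conc / tot)
}

#' Sequence identity between two histones
#'
#' Equal-length pairs are compared position by position; unequal lengths are
#' globally aligned (BLOSUM62, gap open 10 / extend 0.5) first.  Identity is
#' matches over aligned length; differing positions are reported in the
#' mature numbering of the first sequence.
#'
#' @param a,b `histone_protein` objects or plain amino-acid strings.
#' @return list with `identity` (fraction in \[0, 1\]) and `differences`
#'   (integer positions on `a`).
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (inherits(a, "histone_protein")) a$sequence else toupper(a)
  sb <- if (inherits(b, "histone_protein")) b$sequence else toupper(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty sequence")
  if (nchar(sa) == nchar(sb)) {
    ra <- strsplit(sa, "")[[1]]; rb <- strsplit(sb, "")[[1]]
    diffs <- which(ra != rb)
    return(list(identity = 1 - length(diffs) / length(ra),
                differences = diffs))
  }
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  apos <- cumsum(pa != "-")
  mism <- pa != pb
  diffs <- unique(apos[mism & pa != "-"])
  list(identity = sum(!mism) / length(pa), differences = diffs)
}

#' Two-sided Fisher exact comparison of two site counts
#'
#' Compares `k1` acetylated of `n1` lysines against `k2` of `n2` by the
#' exact hypergeometric test on the 2x2 table.
#'
#' @param k1,n1,k2,n2 non-negative counts with `k <= n`.
#' @return two-sided p-value.
#' @export
count_comparison_fisher <- function(k1, n1, k2, n2) {
  v <- c(k1, n1, k2, n2)
  if (any(!is.finite(v)) || any(v < 0)) stop("counts must be non-negative")
  if (k1 > n1 || k2 > n2) stop("k must not exceed n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Write / read a peptide set as tab-separated text
#'
#' Columns: `id`, `positions` (comma-joined), `window`, `label`.
#' @param peptides a `lysine_peptides` data frame.
#' @param path output path.
#' @export
write_peptides <- function(peptides, path) {
  df <- data.frame(
    id = peptides$peptide_id,
    positions = vapply(peptides$positions, paste, character(1), collapse = ","),
    window = peptides$window,
    label = peptides$label,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
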