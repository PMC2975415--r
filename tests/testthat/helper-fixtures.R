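# Programmatic fixtures shared across test files.  Everything is built in
# code at test time; nothing is read from disk except what a test itself
# writes to a tempfile.

# Write a small FASTA + annotation pair and return the two paths.
write_toy_inputs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "histones.fasta")
  ann <- file.path(dir, "sites.tsv")
  writeLines(c(
    ">hA species=human family=H4 variant=H4",
    "MSGRGKGGKGLGKGGAKRHRKVLRD",
    ">hB species=human family=H3 variant=H3.1",
    "MARTKQTARKSTGGKAPRKQLATKA",
    ">hC species=human family=H2A variant=H2A.1",
    "MAGGKAGKDSGKAKTKAVSRSQRAG"), fasta)
  df <- data.frame(
    id = c("hA", "hA", "hA", "hB", "hB", "hC"),
    position = c(5, 8, 12, 4, 9, 4),
    label = c("P", "P", "N", "P", "N", "N"))
  write.table(df, ann, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, annotation = ann)
}

# A labeled motif-family training set in the clustering regime the
# classifier assumes (tight same-motif clusters, distant cross-motif).
toy_training <- function(seed = 1, n_proteins = 4, lysines = 6,
                         mutation_rate = 0.05) {
  generate_histone_family(family_spec(
    n_proteins = n_proteins, lysines_per_protein = lysines,
    mutation_rate = mutation_rate, seed = seed))
}

# Deterministically corrupt `k` flank positions of a motif (never the
# central lysine), used to build queries that miss the high cutoff but
# still lean toward their source motif.
perturb_motif <- function(motif, k, replacement = "W") {
  res <- strsplit(motif, "")[[1]]
  mid <- (length(res) + 1) / 2
  slots <- setdiff(seq_along(res), mid)
  res[slots[seq_len(k)]] <- replacement
  paste(res, collapse = "")
}

# Build a synthetic protein whose lysine windows are given verbatim.
protein_from_windows <- function(id, windows, family = "SYN",
                                 labels = NULL, spacer = 4) {
  len <- unique(nchar(windows))
  stopifnot(length(len) == 1, len %% 2 == 1)
  flank <- (len - 1) / 2
  gap <- strrep("G", spacer)
  seq <- paste0(gap, paste(windows, collapse = gap), gap)
  offset <- spacer + flank + 1
  step <- len + spacer
  pos <- offset + step * (seq_along(windows) - 1)
  lab <- if (is.null(labels)) NULL else stats::setNames(labels, pos)
  p <- new_histone_protein(id, seq, species = "synthetic", family = family,
                           variant = id, labels = lab %||% character())
  list(protein = p, positions = pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Toy nucleosome-like structure: two symmetric copies of a reference chain
# whose P-labeled lysines sit on an "acetylable" ellipsoid and N-labeled on
# an "un-acetylable" one, plus a query chain with configurable per-site
# placement.  Returns paths, histones, catalog spec and the planted truth.
toy_structure_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                  p_motif = "GGAAKAAGG",
                                  n_motif = "EEDLKLDEE",
                                  query_windows = NULL,
                                  query_regions = NULL) {
  regA <- list(center = c(0, 0, 0), radii = c(8, 10, 12))    # acetylable
  regB <- list(center = c(60, 0, 0), radii = c(8, 10, 12))   # un-acetylable
  on_shell <- function(reg, n, seed) {
    kacpred:::with_seed(seed, {
      s <- matrix(stats::rnorm(3 * n), n, 3)
      s <- s / sqrt(rowSums(s^2))
      sweep(s %*% diag(reg$radii), 2, reg$center, "+")
    })
  }
  # one distinguishing first residue per copy so every flanking window is
  # unique on the chain (exact-match mapping would otherwise be ambiguous)
  tags <- c("A", "C", "D", "F", "H")
  p_wins <- paste0(tags, substring(p_motif, 2))
  n_wins <- paste0(tags, substring(n_motif, 2))
  ref <- protein_from_windows(
    "ref01", c(p_wins, n_wins), family = "REF",
    labels = c(rep("P", 5), rep("N", 5)))
  ppos <- ref$positions[1:5]; npos <- ref$positions[6:10]
  chains <- list()
  for (copy in 1:2) {
    ptsA <- on_shell(regA, 5, seed = 10 + copy)
    ptsB <- on_shell(regB, 5, seed = 20 + copy)
    nz <- data.frame(position = c(ppos, npos),
                     x = c(ptsA[, 1], ptsB[, 1]),
                     y = c(ptsA[, 2], ptsB[, 2]),
                     z = c(ptsA[, 3], ptsB[, 3]))
    chains[[c("A", "B")[copy]]] <- list(seq = ref$protein$sequence, nz = nz)
  }
  qry <- NULL
  if (!is.null(query_windows)) {
    qry <- protein_from_windows("qry01", query_windows, family = "QRY")
    qnz <- do.call(rbind, lapply(seq_along(query_regions), function(i) {
      reg <- switch(query_regions[i], A = regA, B = regB, none = NULL)
      if (is.null(reg)) return(NULL)
      pt <- on_shell(reg, 1, seed = 100 + i)
      data.frame(position = qry$positions[i], x = pt[1], y = pt[2], z = pt[3])
    }))
    chains[["Q"]] <- list(seq = qry$protein$sequence, nz = qnz)
  }
  pdb <- file.path(dir, "toy_nucleosome.pdb")
  write_toy_pdb(pdb, chains)
  spec <- data.frame(
    group = c(rep(1L, 5), rep(2L, 5)),
    family = "REF",
    position = c(ppos, npos),
    polarity = c(rep("acetylable", 5), rep("un_acetylable", 5)))
  list(pdb = pdb, ref = ref, qry = qry, catalog_spec = spec,
       regions = list(A = regA, B = regB))
}
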