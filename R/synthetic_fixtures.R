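#' Synthetic histone families and epsilon-N point clouds
#'
#' @description
#' Generators that reproduce the statistical structure the predictor
#' assumes, so every module is testable without downloads: families of
#' short proteins whose lysine flanking windows are mutated copies of
#' class-specific motifs (acetylable versus not), and 3D epsilon-N point
#' clouds concentrated on configurable ellipsoid shells, written out as
#' minimal valid PDB files.  All generators are pure functions of their
#' spec, seed included.
#'
#' @name synthetic_fixtures
NULL

.AA_NO_K <- setdiff(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], "K")

#' Specification of a synthetic histone family
#'
#' @param n_proteins number of proteins to generate.
#' @param lysines_per_protein lysines (and hence windows) per protein.
#' @param p_motifs,n_motifs character vectors of odd-length motifs with a
#'   central `K`; windows drawn from `p_motifs` are labeled `P`, from
#'   `n_motifs` labeled `N`.
#' @param mutation_rate per-residue substitution probability applied to the
#'   non-central motif residues (in \[0, 0.5)).
#' @param spacing residues between consecutive lysines; defaults to one
#'   more than the motif length so windows never overlap and lysines are
#'   never adjacent.
#' @param seed integer seed.
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_proteins = 6, lysines_per_protein = 8,
                        p_motifs = c("GGAAKAAGG", "RRTAKATRR"),
                        n_motifs = c("EEDLKLDEE"),
                        mutation_rate = 0.05, spacing = NULL, seed = 1) {
  motifs <- c(p_motifs, n_motifs)
  len <- unique(nchar(motifs))
  if (length(len) != 1L || len %% 2 == 0) {
    stop("all motifs must share one odd length")
  }
  mid <- (len + 1) / 2
  if (!all(substring(motifs, mid, mid) == "K")) {
    stop("every motif must carry a central K")
  }
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("mutation_rate must lie in [0, 0.5)")
  }
  structure(list(n_proteins = n_proteins,
                 lysines_per_protein = lysines_per_protein,
                 p_motifs = p_motifs, n_motifs = n_motifs,
                 motif_length = len,
                 mutation_rate = mutation_rate,
                 spacing = spacing %||% (len + 1),
                 seed = seed),
            class = "family_spec")
}

#' Generate a synthetic histone family with planted labels
#'
#' Each lysine's flanking window is a class motif with i.i.d. substitutions
#' at the non-central positions; the rest of the protein is random sequence
#' without lysines, so the planted lysines are the only ones.  Proteins
#' cycle deterministically through the motif set so both classes are always
#' represented.
#'
#' @param spec a [family_spec()].
#' @return list with `histones` (list of `histone_protein` carrying the
#'   planted labels), `labels` (data frame `id`, `position`, `label`) and
#'   `truth` (adds the generating motif per site).
#' @export
generate_histone_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  len <- spec$motif_length
  flank <- (len - 1) / 2
  spacing <- max(spec$spacing, len)
  prot_len <- flank + spec$lysines_per_protein * spacing + flank
  if (len > prot_len) stop("motif longer than protein")
  motifs <- c(spec$p_motifs, spec$n_motifs)
  classes <- c(rep("P", length(spec$p_motifs)), rep("N", length(spec$n_motifs)))
  with_seed(spec$seed, {
    truth <- list(); histones <- list()
    midx_global <- 0L
    for (j in seq_len(spec$n_proteins)) {
      res <- sample(.AA_NO_K, prot_len, replace = TRUE)
      pos <- flank + 1L + spacing * (seq_len(spec$lysines_per_protein) - 1L)
      for (i in seq_len(spec$lysines_per_protein)) {
        midx_global <- midx_global + 1L
        mi <- ((midx_global - 1L) %% length(motifs)) + 1L
        motif <- strsplit(motifs[mi], "")[[1]]
        mut <- stats::runif(len) < spec$mutation_rate
        mut[flank + 1L] <- FALSE
        motif[mut] <- sample(.AA_NO_K, sum(mut), replace = TRUE)
        res[(pos[i] - flank):(pos[i] + flank)] <- motif
        truth[[length(truth) + 1L]] <- data.frame(
          id = sprintf("syn%02d", j), position = pos[i],
          motif = motifs[mi], motif_class = mi, label = classes[mi],
          stringsAsFactors = FALSE)
      }
      tt <- do.call(rbind, truth[(length(truth) - spec$lysines_per_protein + 1L):length(truth)])
      histones[[j]] <- new_histone_protein(
        sprintf("syn%02d", j), paste(res, collapse = ""),
        species = "synthetic", family = "SYN", variant = sprintf("SYN.%d", j),
        labels = stats::setNames(tt$label, tt$position))
    }
    names(histones) <- vapply(histones, `[[`, character(1), "id")
    truth <- do.call(rbind, truth)
    list(histones = histones,
         labels = truth[c("id", "position", "label")],
         truth = truth)
  })
}

#' Specification of a synthetic epsilon-N point cloud
#'
#' @param groups list of group definitions, each a list with `center`
#'   (3-vector), `radii` (3 positive lengths), optional `orientation`
#'   (3x3 rotation, identity by default), `polarity` and `n_points`.
#' @param noise_sd isotropic Gaussian noise added to each point, in the
#'   same units as the coordinates (default 0).
#' @param seed integer seed.
#' @return a `cloud_spec` list.
#' @export
cloud_spec <- function(groups, noise_sd = 0, seed = 1) {
  for (g in groups) {
    stopifnot(length(g$center) == 3, length(g$radii) == 3, all(g$radii > 0))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(groups = groups, noise_sd = noise_sd, seed = seed),
            class = "cloud_spec")
}

#' Generate points on the spec's ellipsoid shells
#'
#' Each point is `center + R %*% diag(radii) %*% s + noise` for a uniform
#' random unit direction `s`.
#'
#' @param spec a [cloud_spec()].
#' @return list with `points` (data frame `group`, `polarity`, `x`, `y`,
#'   `z`) and the originating `spec`.
#' @export
generate_epsilon_cloud <- function(spec) {
  stopifnot(inherits(spec, "cloud_spec"))
  with_seed(spec$seed, {
    pts <- lapply(seq_along(spec$groups), function(gi) {
      g <- spec$groups[[gi]]
      n <- g$n_points %||% 30L
      R <- g$orientation %||% diag(3)
      s <- matrix(stats::rnorm(3 * n), n, 3)
      s <- s / sqrt(rowSums(s^2))
      p <- s %*% diag(g$radii) %*% t(R)
      p <- sweep(p, 2, g$center, "+")
      if (spec$noise_sd > 0) p <- p + matrix(stats::rnorm(3 * n, sd = spec$noise_sd), n, 3)
      data.frame(group = gi, polarity = g$polarity %||% NA_character_,
                 x = p[, 1], y = p[, 2], z = p[, 3],
                 stringsAsFactors = FALSE)
    })
    list(points = do.call(rbind, pts), spec = spec)
  })
}

#' Write a minimal PDB file for synthetic structures
#'
#' Emits standard `ATOM` records: one CA per residue of each chain (laid
#' out on a line, their coordinates carry no meaning) and an NZ atom for
#' each lysine position supplied with coordinates.  The result parses with
#' standard PDB readers and round-trips coordinates at the format's fixed
#' 3-decimal precision.
#'
#' @param path output path.
#' @param chains named list (names = chain ids); each element a list with
#'   `seq` (amino-acid string) and `nz` (data frame `position`, `x`, `y`,
#'   `z`, positions 1-based on `seq`; rows may omit some lysines to emulate
#'   unresolved side chains).
#' @return the path, invisibly.
#' @export
write_toy_pdb <- function(path, chains) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR", X = "UNK")
  lines <- character(0)
  serial <- 0L
  ci <- 0L
  for (cn in names(chains)) {
    ci <- ci + 1L
    ch <- chains[[cn]]
    res <- strsplit(ch$seq, "")[[1]]
    nz <- ch$nz
    for (i in seq_along(res)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, "CA", aa3[[res[i]]], cn, i,
        i * 3.8, ci * 60, 0, 1, 0, "C"))
      if (res[i] == "K" && !is.null(nz) && i %in% nz$position) {
        serial <- serial + 1L
        r <- nz[nz$position == i, , drop = FALSE][1, ]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, "NZ", "LYS", cn, i, r$x, r$y, r$z, 1, 0, "N"))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
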