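#' Nucleosome-level spatial feature
#'
#' @description
#' Acetylability correlates with where a lysine sits in the nucleosome.
#' This module reads lysine side-chain epsilon-N (`NZ`) coordinates from a
#' PDB structure, locates each histone lysine on the structure chains by
#' exact flanking-peptide matching (never by PDB residue numbers, whose
#' conventions vary), fits an ellipsoid `(x - c)^T A (x - c) = 1` to each of
#' five acetylability-associated site groups by linear least squares, and
#' scores a site by its numeric distances to the acetylable versus
#' un-acetylable regions with the same max-min decision rule used for
#' peptides.
#'
#' @name nucleosome_geometry
NULL

#' Extract lysine epsilon-N atoms from a PDB structure
#'
#' One record per `NZ` atom of a lysine residue.  Lysines whose side chain
#' is unresolved (no `NZ`) are skipped and counted in the `n_missing_nz`
#' attribute (also reported via a message).
#'
#' @param structure path to a PDB file, or a `bio3d` `pdb` object.
#' @return data frame `chain`, `resno`, `x`, `y`, `z` with attribute
#'   `n_missing_nz`.
#' @export
extract_epsilon_n <- function(structure) {
  pdb <- if (inherits(structure, "pdb")) structure else bio3d::read.pdb(structure)
  at <- pdb$atom
  lys <- at[at$resid == "LYS", , drop = FALSE]
  if (nrow(at) == 0 || length(unique(at$chain)) == 0) stop("structure has no chains")
  nz <- lys[lys$elety == "NZ", , drop = FALSE]
  res_all <- unique(lys[c("chain", "resno")])
  res_nz <- unique(nz[c("chain", "resno")])
  n_missing <- nrow(res_all) - nrow(res_nz)
  if (n_missing > 0) {
    message(sprintf("%d lysine residue(s) lack an NZ atom and were skipped",
                    n_missing))
  }
  out <- data.frame(chain = nz$chain, resno = nz$resno,
                    x = nz$x, y = nz$y, z = nz$z, stringsAsFactors = FALSE)
  attr(out, "n_missing_nz") <- n_missing
  out
}

# Per-chain sequences from CA atoms, with the residue number of each
# sequence index retained so matches can be tied back to NZ atoms.
.chain_sequences <- function(pdb) {
  at <- pdb$atom
  ca <- at[at$elety == "CA" & !is.na(at$chain), , drop = FALSE]
  lapply(split(ca, ca$chain), function(cc) {
    cc <- cc[order(cc$resno), , drop = FALSE]
    cc <- cc[!duplicated(cc$resno), , drop = FALSE]
    list(seq = paste(bio3d::aa321(cc$resid), collapse = ""),
         resno = cc$resno)
  })
}

#' Map histone lysines onto structure chains by peptide matching
#'
#' Each lysine is located on each chain by exact matching of its flanking
#' peptide (up to `min_match` residues per side, truncated at termini); on
#' failure the window is shrunk one residue per side at a time, down to a
#' single flanking residue.  A window matching more than one chain position
#' flags the site ambiguous on that chain and excludes it.  A mapped
#' position contributes an atom only when the chain residue is a lysine
#' with a resolved `NZ`.
#'
#' @param histones list of `histone_protein` objects.
#' @param structure path to a PDB file or a `bio3d` `pdb` object.
#' @param min_match maximum flank used for matching (default 8).
#' @return data frame `id`, `family`, `position`, `chain`, `resno`, `x`,
#'   `y`, `z`, `status` (`mapped`, `ambiguous`, `unmapped`, `no_nz`): one
#'   row per (site, chain) outcome, possibly several mapped copies per site
#'   for symmetric octamer chains.
#' @export
map_sites_to_structure <- function(histones, structure, min_match = 8) {
  pdb <- if (inherits(structure, "pdb")) structure else bio3d::read.pdb(structure)
  chains <- .chain_sequences(pdb)
  atoms <- suppressMessages(extract_epsilon_n(pdb))
  akey <- paste(atoms$chain, atoms$resno)
  rows <- list()
  for (h in histones) {
    seqchr <- h$sequence
    L <- nchar(seqchr)
    for (p in lysine_positions(h)) {
      for (cn in names(chains)) {
        ch <- chains[[cn]]
        hit <- NULL; ambiguous <- FALSE
        for (w in seq(min_match, 1L)) {
          s <- max(1L, p - w); e <- min(L, p + w)
          win <- substring(seqchr, s, e)
          offs <- p - s  # 0-based offset of K within the window
          m <- gregexpr(win, ch$seq, fixed = TRUE)[[1]]
          m <- m[m > 0]
          if (length(m) > 1L) { ambiguous <- TRUE; break }
          if (length(m) == 1L) { hit <- m + offs; break }
        }
        if (ambiguous) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = h$id, family = h$family, position = p, chain = cn,
            resno = NA_integer_, x = NA_real_, y = NA_real_, z = NA_real_,
            status = "ambiguous", stringsAsFactors = FALSE)
        } else if (!is.null(hit)) {
          resno <- ch$resno[hit]
          ai <- match(paste(cn, resno), akey)
          if (substring(ch$seq, hit, hit) != "K" || is.na(ai)) {
            status <- "no_nz"
            rows[[length(rows) + 1L]] <- data.frame(
              id = h$id, family = h$family, position = p, chain = cn,
              resno = resno, x = NA_real_, y = NA_real_, z = NA_real_,
              status = status, stringsAsFactors = FALSE)
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              id = h$id, family = h$family, position = p, chain = cn,
              resno = resno, x = atoms$x[ai], y = atoms$y[ai],
              z = atoms$z[ai], status = "mapped", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(), family = character(),
                      position = integer(), chain = character(),
                      resno = integer(), x = numeric(), y = numeric(),
                      z = numeric(), status = character())
  }
  out
}

#' Fit an ellipsoid to a 3D point cloud
#'
#' Least-squares fit of the surface `(p - c)^T A (p - c) = 1`.  With at
#' least 9 points the center is estimated from the linear terms of a full
#' quadric fit (`p^T A p + b^T p = 1`, `c = -A^{-1} b / 2`), which recovers
#' a noiseless ellipsoid exactly even when the sampled points cover the
#' shell unevenly; with 6-8 points the center is fixed at the centroid and
#' only the six free entries of the symmetric `A` are fitted.  Eigenvalues
#' of the fitted `A` are clamped to at least `eps` so `A` is positive
#' definite; principal radii are the inverse square roots of the
#' eigenvalues.
#'
#' @param points numeric matrix (>= 6 rows, 3 columns).
#' @param eps eigenvalue floor (default 1e-8).
#' @return object of class `ellipsoid_region`: `center`, `A`, `radii`
#'   (sorted decreasing), `axes` (eigenvectors, columns matching `radii`),
#'   `residual` (RMS of `q(p) - 1`), `n_points`, `clamped`, `fallback`.
#' @export
fit_ellipsoid <- function(points, eps = 1e-8) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("insufficient points: ellipsoid fit needs >= 6")
  quad_cols <- function(q) {
    cbind(q[, 1]^2, q[, 2]^2, q[, 3]^2,
          2 * q[, 1] * q[, 2], 2 * q[, 1] * q[, 3], 2 * q[, 2] * q[, 3])
  }
  assemble <- function(theta) {
    matrix(c(theta[1], theta[4], theta[5],
             theta[4], theta[2], theta[6],
             theta[5], theta[6], theta[3]), 3, 3)
  }
  centroid <- colMeans(points)
  q0 <- sweep(points, 2, centroid)
  if (nrow(points) >= 9) {
    # full quadric: p^T A p + b^T p = 1 in centroid-relative coordinates
    M <- cbind(quad_cols(q0), q0)
    qr_m <- qr(M)
    if (qr_m$rank < 9) {
      stop(sprintf(
        "rank-deficient ellipsoid design (rank %d, condition %.3g): %s",
        qr_m$rank, kappa(M), "points are degenerate after centering"))
    }
    theta <- qr.coef(qr_m, rep(1, nrow(M)))
    A <- assemble(theta[1:6])
    b <- theta[7:9]
    cen_rel <- tryCatch(-solve(A, b) / 2, error = function(e) c(0, 0, 0))
    s <- 1 + as.numeric(t(cen_rel) %*% A %*% cen_rel)
    if (is.finite(s) && s > 0) A <- A / s
    center <- centroid + cen_rel
  } else {
    M <- quad_cols(q0)
    qr_m <- qr(M)
    if (qr_m$rank < 6) {
      stop(sprintf(
        "rank-deficient ellipsoid design (rank %d, condition %.3g): %s",
        qr_m$rank, kappa(M), "points are degenerate after centering"))
    }
    theta <- qr.coef(qr_m, rep(1, nrow(M)))
    A <- assemble(theta)
    center <- centroid
  }
  q <- sweep(points, 2, center)
  # residual of the least-squares quadric itself, before any clamping
  resid <- sqrt(mean((rowSums((q %*% A) * q) - 1)^2))
  eg <- eigen(A, symmetric = TRUE)
  clamped <- any(eg$values < eps)
  vals <- pmax(eg$values, eps)
  A <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  radii <- 1 / sqrt(vals)
  structure(list(center = center, A = A, radii = radii,
                 axes = eg$vectors, residual = resid,
                 n_points = nrow(points), clamped = clamped,
                 fallback = FALSE),
            class = "ellipsoid_region")
}

#' @export
print.ellipsoid_region <- function(x, ...) {
  cat(sprintf("<ellipsoid_region>%s center=(%.2f, %.2f, %.2f), radii=(%.2f, %.2f, %.2f), n=%d\n",
              if (x$fallback) " [sphere fallback]" else "",
              x$center[1], x$center[2], x$center[3],
              x$radii[1], x$radii[2], x$radii[3], x$n_points))
  invisible(x)
}

# Sphere fallback for groups with too few pooled atoms: centroid plus the
# RMS radius of the members.
.sphere_region <- function(points) {
  points <- as.matrix(points)
  center <- colMeans(points)
  r <- sqrt(mean(rowSums(sweep(points, 2, center)^2)))
  if (!is.finite(r) || r <= 0) r <- 1
  structure(list(center = center, A = diag(1 / r^2, 3), radii = rep(r, 3),
                 axes = diag(3), residual = NA_real_,
                 n_points = nrow(points), clamped = FALSE, fallback = TRUE),
            class = "ellipsoid_region")
}

#' Numeric distance from a point to an ellipsoid surface
#'
#' The surface is sampled as `center + A^(-1/2) s` over a deterministic
#' Fibonacci lattice of unit directions `s` (the seed only rotates the
#' lattice offset); the distance is the minimum Euclidean distance from the
#' point to the samples.  The sampling error is bounded by roughly
#' `2 * pi * max(radii) / sqrt(n_surface_samples)`.
#'
#' @param p numeric 3-vector.
#' @param region an `ellipsoid_region`.
#' @param n_surface_samples number of surface samples (default 4096).
#' @param seed integer controlling the lattice offset (default 1).
#' @return non-negative distance (same units as the coordinates).
#' @export
point_to_ellipsoid_distance <- function(p, region, n_surface_samples = 4096,
                                        seed = 1) {
  stopifnot(inherits(region, "ellipsoid_region"), length(p) == 3)
  s <- fibonacci_sphere(n_surface_samples, offset = seed_offset(seed))
  eg <- eigen(region$A, symmetric = TRUE)
  half_inv <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  surf <- s %*% half_inv
  surf <- sweep(surf, 2, region$center, "+")
  d2 <- rowSums(sweep(surf, 2, as.numeric(p))^2)
  sqrt(min(d2))
}

#' Default acetylability-associated region catalog
#'
#' The five site groups whose pooled epsilon-N positions define the spatial
#' regions: group 1 (H3K37, H3K56, H4K31, H4K44, H4K59; acetylable, near
#' the DNA-binding boundary), group 2 (H3K115, H3K122; un-acetylable,
#' mid DNA-binding), group 3 (H2BK40, H2BK43, H2BK105, H2BK113, H2BK117,
#' H2BK122; un-acetylable, distal from DNA), group 4 (H4K77, H4K79;
#' acetylable) and group 5 (H4K91; acetylable, nucleosome center).  The
#' H2BK31 pair is deliberately not a feature group.
#'
#' @return data frame `group`, `family`, `position`, `polarity`.
#' @export
default_catalog_spec <- function() {
  data.frame(
    group = c(rep(1L, 5), rep(2L, 2), rep(3L, 6), rep(4L, 2), 5L),
    family = c("H3", "H3", "H4", "H4", "H4",
               "H3", "H3",
               rep("H2B", 6),
               "H4", "H4", "H4"),
    position = c(37L, 56L, 31L, 44L, 59L,
                 115L, 122L,
                 40L, 43L, 105L, 113L, 117L, 122L,
                 77L, 79L, 91L),
    polarity = c(rep("acetylable", 5), rep("un_acetylable", 2),
                 rep("un_acetylable", 6), rep("acetylable", 2),
                 "acetylable"),
    stringsAsFactors = FALSE)
}

#' Read a region catalog specification from a YAML config
#'
#' Expects a top-level `groups` list, each with `group`, `polarity` and a
#' `sites` list of `family`/`position` pairs; overrides the built-in
#' catalog membership and polarity.
#'
#' @param path YAML file path.
#' @return data frame in the format of [default_catalog_spec()].
#' @export
read_catalog_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading catalog configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y$groups, function(g) {
    do.call(rbind, lapply(g$sites, function(s) {
      data.frame(group = as.integer(g$group), family = s$family,
                 position = as.integer(s$position), polarity = g$polarity,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Fit the region catalog from mapped epsilon-N atoms
#'
#' Pools the mapped atoms of every member site of each group (all symmetric
#' copies) and fits an ellipsoid; groups with fewer than 6 pooled atoms get
#' an isotropic sphere through the RMS radius, flagged `fallback`.  A
#' catalog site with no mapped atom at all is an error naming the site.
#'
#' @param mapping output of [map_sites_to_structure()].
#' @param catalog_spec site group table ([default_catalog_spec()] by
#'   default).
#' @return object of class `region_catalog`: list of regions (each an
#'   `ellipsoid_region` plus `group_id`, `polarity`, `members`).
#' @export
build_region_catalog <- function(mapping, catalog_spec = default_catalog_spec()) {
  mapped <- mapping[mapping$status == "mapped", , drop = FALSE]
  regions <- lapply(sort(unique(catalog_spec$group)), function(g) {
    spec_g <- catalog_spec[catalog_spec$group == g, , drop = FALSE]
    pts <- list()
    for (i in seq_len(nrow(spec_g))) {
      sel <- mapped$family == spec_g$family[i] &
        mapped$position == spec_g$position[i]
      if (!any(sel)) {
        stop(sprintf("catalog site %sK%d (group %d) has no mapped epsilon-N atom",
                     spec_g$family[i], spec_g$position[i], g))
      }
      pts[[i]] <- as.matrix(mapped[sel, c("x", "y", "z")])
    }
    pts <- do.call(rbind, pts)
    reg <- if (nrow(pts) >= 6) fit_ellipsoid(pts) else .sphere_region(pts)
    reg$group_id <- g
    reg$polarity <- spec_g$polarity[1]
    reg$members <- paste0(spec_g$family, "K", spec_g$position)
    reg
  })
  structure(list(regions = regions, spec = catalog_spec),
            class = "region_catalog")
}

#' @export
print.region_catalog <- function(x, ...) {
  for (r in x$regions) {
    cat(sprintf("group %d (%s%s): %d atoms, radii %.2f/%.2f/%.2f  [%s]\n",
                r$group_id, r$polarity, if (r$fallback) ", sphere" else "",
                r$n_points, r$radii[1], r$radii[2], r$radii[3],
                paste(r$members, collapse = " ")))
  }
  invisible(x)
}

#' Serialize a fitted region catalog to JSON
#' @param catalog a `region_catalog`.
#' @param path output path.
#' @export
write_region_catalog <- function(catalog, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing catalogs requires the 'jsonlite' package")
  }
  out <- lapply(catalog$regions, function(r) {
    list(group = r$group_id, polarity = r$polarity,
         center = as.numeric(r$center), matrix_A = as.numeric(t(r$A)),
         radii = as.numeric(r$radii), members = r$members,
         fallback = r$fallback)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Spatial max-min decision for one site
#'
#' The site's distance to a region is the minimum over its symmetric-copy
#' atoms of the numeric point-to-surface distance; the score applies the
#' same max-min rule as the peptide classifier,
#' `alpha * min(d, un-acetylable) - beta * min(d, acetylable) - I`, with a
#' positive score predicting acetylable.
#'
#' @param site_atoms numeric matrix of the site's epsilon-N coordinates
#'   (one row per symmetric copy).
#' @param catalog a fitted `region_catalog`.
#' @param cls a [classifier_params()] list.
#' @param n_surface_samples surface samples per region (default 4096).
#' @param seed lattice offset seed (default 1).
#' @return list with `score`, `label` and per-region `distances`.
#' @export
spatial_decision <- function(site_atoms, catalog, cls = classifier_params(),
                             n_surface_samples = 4096, seed = 1) {
  site_atoms <- matrix(as.numeric(as.matrix(site_atoms)), ncol = 3)
  if (nrow(site_atoms) == 0) stop("site has no epsilon-N atoms")
  dists <- vapply(catalog$regions, function(r) {
    min(apply(site_atoms, 1, point_to_ellipsoid_distance, region = r,
              n_surface_samples = n_surface_samples, seed = seed))
  }, numeric(1))
  pol <- vapply(catalog$regions, `[[`, character(1), "polarity")
  if (!all(c("acetylable", "un_acetylable") %in% pol)) {
    stop("catalog must contain both polarities")
  }
  score <- cls$alpha * min(dists[pol == "un_acetylable"]) -
    cls$beta * min(dists[pol == "acetylable"]) - cls$intercept
  list(score = score, label = if (score > 0) "P" else "N",
       distances = stats::setNames(dists,
                                   paste0("group", vapply(catalog$regions,
                                                          `[[`, integer(1),
                                                          "group_id"))))
}
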