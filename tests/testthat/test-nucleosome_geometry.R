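test_that("extract_epsilon_n reads NZ atoms and counts missing side chains", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "toy.pdb")
  nz <- data.frame(position = c(3, 9), x = c(1.5, -2.25), y = c(0.125, 4),
                   z = c(-3, 7.5))
  write_toy_pdb(f, list(A = list(seq = "AAKAAKAAKAA", nz = nz)))
  # lysines at 3, 6, 9; position 6 has no NZ -> skipped, logged
  expect_message(at <- extract_epsilon_n(f), "1 lysine")
  expect_equal(nrow(at), 2)
  expect_equal(attr(at, "n_missing_nz"), 1)
  expect_equal(at$x, nz$x, tolerance = 1e-3)
  expect_equal(at$resno, c(3, 9))
})

test_that("toy PDB coordinates round-trip at fixed-width precision", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rt.pdb")
  set.seed(41)
  nz <- data.frame(position = c(3, 6, 9), x = rnorm(3, 0, 20),
                   y = rnorm(3, 0, 20), z = rnorm(3, 0, 20))
  write_toy_pdb(f, list(A = list(seq = "AAKAAKAAKAA", nz = nz),
                        B = list(seq = "AAKAAKAAKAA", nz = nz)))
  at <- extract_epsilon_n(f)
  expect_equal(nrow(at), 6)  # two symmetric chains
  expect_equal(at$x[at$chain == "A"], nz$x, tolerance = 5e-4)
  expect_equal(at$z[at$chain == "B"], nz$z, tolerance = 5e-4)
})

test_that("map_sites_to_structure maps by peptide identity, shrinking at mismatches", {
  dir <- withr::local_tempdir()
  h <- new_histone_protein("h3x", "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHR",
                           family = "H3")
  kpos <- lysine_positions(h)
  nz <- data.frame(position = kpos, x = kpos, y = 0, z = 0)
  f <- file.path(dir, "map.pdb")
  # chain B carries 3 substitutions far from any lysine window center
  seqB <- h$sequence
  substr(seqB, 33, 33) <- "E"
  write_toy_pdb(f, list(A = list(seq = h$sequence, nz = nz),
                        B = list(seq = seqB, nz = nz)))
  mp <- map_sites_to_structure(list(h), f, min_match = 8)
  mapped <- mp[mp$status == "mapped", ]
  # every lysine maps on chain A at its own position
  a <- mapped[mapped$chain == "A", ]
  expect_setequal(a$position, kpos)
  expect_equal(a$resno, a$position)
  # the substitution at 33 sits within the full window of K36/K37 but the
  # shrinking match still finds them on chain B
  b <- mapped[mapped$chain == "B", ]
  expect_true(all(c(36, 37) %in% b$position))
})

test_that("repeated peptides are flagged ambiguous and excluded", {
  dir <- withr::local_tempdir()
  # the K window occurs twice in the chain
  h <- new_histone_protein("amb", "GGGAKAGGG")
  f <- file.path(dir, "amb.pdb")
  ch <- "GGGAKAGGGGGGAKAGGG"
  nz <- data.frame(position = c(5, 14), x = 0, y = 0, z = 0)
  write_toy_pdb(f, list(A = list(seq = ch, nz = nz)))
  mp <- map_sites_to_structure(list(h), f, min_match = 8)
  expect_identical(unique(mp$status), "ambiguous")
})

test_that("fit_ellipsoid recovers spheres exactly and general radii noiselessly", {
  # 12 points on the unit sphere with centroid exactly at the origin
  s6 <- rbind(diag(3), -diag(3))
  d4 <- matrix(c(1, 1, 1, 1, -1, 1, -1, 1, 1, 1, 1, -1), 4, 3,
               byrow = TRUE) / sqrt(3)
  pts <- rbind(s6, d4, -d4[1:2, ])
  f <- fit_ellipsoid(pts)
  expect_lt(max(abs(f$A - diag(3))), 1e-6)
  expect_lt(max(abs(f$radii - 1)), 1e-6)
  # radii (1,2,3), off-center, 30 random surface points: within 1%
  set.seed(5)
  u <- matrix(rnorm(90), 30, 3); u <- u / sqrt(rowSums(u^2))
  p <- sweep(u %*% diag(c(1, 2, 3)), 2, c(4, -2, 7), "+")
  f2 <- fit_ellipsoid(p)
  expect_lt(max(abs(sort(f2$radii) - c(1, 2, 3)) / c(1, 2, 3)), 0.01)
  expect_equal(f2$center, c(4, -2, 7), tolerance = 1e-6)
  expect_error(fit_ellipsoid(p[1:5, ]), "insufficient")
  # coplanar points cannot define an ellipsoid
  flat <- cbind(matrix(rnorm(40), 20, 2), 0)
  expect_error(fit_ellipsoid(flat), "rank-deficient")
})

test_that("fit_ellipsoid is rotation-equivariant", {
  set.seed(6)
  u <- matrix(rnorm(120), 40, 3); u <- u / sqrt(rowSums(u^2))
  p <- u %*% diag(c(2, 5, 9))
  f0 <- fit_ellipsoid(p)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    fr <- fit_ellipsoid(p %*% t(R))
    expect_equal(sort(fr$radii), sort(f0$radii), tolerance = 1e-8)
    # the rotated A equals R A R^T
    expect_lt(max(abs(fr$A - R %*% f0$A %*% t(R))), 1e-8)
  }
})

test_that("six points in general position are interpolated with zero residual", {
  set.seed(9)
  u <- matrix(rnorm(18), 6, 3); u <- u / sqrt(rowSums(u^2))
  f <- fit_ellipsoid(u %*% diag(c(2, 2, 3)))
  expect_lt(f$residual, 1e-10)
})

test_that("point-to-ellipsoid distance matches closed forms and converges", {
  s6 <- rbind(diag(3), -diag(3)) * 2
  d4 <- matrix(c(1, 1, 1, 1, -1, 1, -1, 1, 1, 1, 1, -1), 4, 3,
               byrow = TRUE) / sqrt(3) * 2
  sphere <- fit_ellipsoid(rbind(s6, d4, -d4[1:2, ]))  # radius-2 sphere
  bound <- function(n) 2 * pi * max(sphere$radii) / sqrt(n)
  expect_equal(point_to_ellipsoid_distance(c(0, 0, 0), sphere, 4096), 2,
               tolerance = bound(4096) / 2)
  expect_lt(point_to_ellipsoid_distance(c(2, 0, 0), sphere, 4096), bound(4096))
  # doubling samples never worsens the estimate beyond the sampling bound
  p <- c(5, 1, -2)
  d1 <- point_to_ellipsoid_distance(p, sphere, 2048)
  d2 <- point_to_ellipsoid_distance(p, sphere, 4096)
  expect_lt(d2 - d1, bound(2048))
  # dense random-sampling oracle within 1%
  set.seed(7)
  u <- matrix(rnorm(90), 30, 3); u <- u / sqrt(rowSums(u^2))
  reg <- fit_ellipsoid(sweep(u %*% diag(c(3, 5, 8)), 2, c(1, 2, 3), "+"))
  for (pt in list(c(20, 0, 0), c(1, 2, 3), c(-6, 9, 0))) {
    d_pkg <- point_to_ellipsoid_distance(pt, reg, 65536)
    d_orc <- oracle_ellipsoid_distance(pt, reg$center, reg$A, n = 1e6)
    expect_equal(d_pkg, d_orc, tolerance = 0.01 * max(d_orc, 0.5),
                 label = paste("point", paste(pt, collapse = ",")))
  }
})

test_that("region catalog pools symmetric copies, falls back to spheres, and errors on unmapped sites", {
  fx <- toy_structure_fixture()
  mp <- map_sites_to_structure(list(fx$ref$protein), fx$pdb, min_match = 8)
  cat5 <- build_region_catalog(mp, fx$catalog_spec)
  expect_length(cat5$regions, 2)
  for (r in cat5$regions) {
    expect_false(r$fallback)          # 10 pooled atoms per group
    expect_equal(r$n_points, 10)
  }
  # radii recovered within tolerance of the planted shells (10 points)
  pol <- vapply(cat5$regions, `[[`, character(1), "polarity")
  regA <- cat5$regions[[which(pol == "acetylable")]]
  expect_equal(sort(regA$radii), sort(fx$regions$A$radii), tolerance = 0.25)
  # a group with < 6 atoms gets the sphere fallback
  spec_small <- fx$catalog_spec[c(1, 6), ]
  spec_small$group <- c(1L, 2L)
  mp_small <- mp[mp$position %in% spec_small$position & mp$chain == "A", ]
  cat_small <- build_region_catalog(mp_small, spec_small)
  expect_true(all(vapply(cat_small$regions, `[[`, logical(1), "fallback")))
  # unmapped catalog site is a named hard error
  spec_bad <- rbind(fx$catalog_spec,
                    data.frame(group = 3L, family = "REF", position = 9999L,
                               polarity = "acetylable"))
  expect_error(build_region_catalog(mp, spec_bad), "REFK9999")
})

test_that("spatial_decision applies the max-min rule over region distances", {
  # two spheres: acetylable at origin (r=2), un-acetylable at (10,0,0) (r=2)
  mk_sphere <- function(center, r, pol, gid) {
    structure(list(center = center, A = diag(1 / r^2, 3), radii = rep(r, 3),
                   axes = diag(3), residual = 0, n_points = 6,
                   clamped = FALSE, fallback = TRUE, group_id = gid,
                   polarity = pol, members = "X"),
              class = "ellipsoid_region")
  }
  cat2 <- structure(list(regions = list(
    mk_sphere(c(0, 0, 0), 2, "acetylable", 1L),
    mk_sphere(c(10, 0, 0), 2, "un_acetylable", 2L)), spec = NULL),
    class = "region_catalog")
  # atom on the acetylable surface: d_P ~ 0, d_N ~ 6 -> score ~ 6 -> P
  sd1 <- spatial_decision(matrix(c(2, 0, 0), 1), cat2)
  expect_equal(sd1$score, 6, tolerance = 0.2)
  expect_identical(sd1$label, "P")
  # exactly equidistant configuration (coincident opposite-polarity
  # spheres): score exactly 0 -> N by the tie rule
  cat_tie <- structure(list(regions = list(
    mk_sphere(c(0, 0, 0), 2, "acetylable", 1L),
    mk_sphere(c(0, 0, 0), 2, "un_acetylable", 2L)), spec = NULL),
    class = "region_catalog")
  sd2 <- spatial_decision(matrix(c(5, 0, 0), 1), cat_tie)
  expect_identical(sd2$score, 0)
  expect_identical(sd2$label, "N")
  # min over symmetric copies: a second far atom cannot worsen the site
  sd3 <- spatial_decision(rbind(c(2, 0, 0), c(100, 0, 0)), cat2)
  expect_equal(sd3$score, sd1$score, tolerance = 1e-9)
})
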