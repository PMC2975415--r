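# Independent oracles used to freeze expected values.  Each one is a direct,
# slow re-derivation that shares no code path with the package functions it
# checks.

# Smith-Waterman local alignment with affine gaps by explicit Gotoh dynamic
# programming; a gap of length L costs open + L * extend.
oracle_sw <- function(a, b, open = 10, extend = 0.5, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      sc <- mat[ra[i - 1], rb[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sc, Ix[i - 1, j - 1] + sc,
                     Iy[i - 1, j - 1] + sc)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Naive agglomerative complete-linkage clustering straight from the
# definition: at each step merge the cluster pair with minimal maximum
# pairwise member distance.  Returns merge heights and the leaf partition
# after each merge.
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      link <- max(d[clusters[[i]], clusters[[j]]])
      if (link < best[1]) best <- c(link, i, j)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    heights <- c(heights, best[1])
    mem <- integer(n)
    for (ci in seq_along(clusters)) mem[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- mem
  }
  list(heights = heights, partitions = partitions)
}

# TRUE when two membership vectors describe the same partition.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Two-sided Fisher p by full hypergeometric enumeration over tables with
# the observed margins, using only choose() arithmetic.
oracle_fisher <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  xs <- max(0, k - n2):min(n1, k)
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  pobs <- probs[xs == k1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Direct entropy arithmetic for the information gain ratio of binary labels
# given a membership vector.
oracle_gain_ratio <- function(mem, labels) {
  H <- function(v) {
    p <- table(v) / length(v); p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(labels)
  ig <- H(labels) - sum(vapply(split(labels, mem), function(g) {
    length(g) / n * H(g)
  }, numeric(1)))
  sizes <- table(mem)
  si <- -sum(sizes / n * log2(sizes / n))
  if (si <= 0) 0 else max(0, ig) / si
}

# All set partitions of n elements as membership vectors (restricted growth
# strings); 203 partitions for n = 6.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in 1:(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0)
  out
}

# All permutations of a vector (n <= 5 in the tests).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Dense random-direction surface sampling for point-to-ellipsoid distance;
# independent of the package's deterministic lattice.
oracle_ellipsoid_distance <- function(p, center, A, n = 1e6) {
  eg <- eigen(A, symmetric = TRUE)
  half_inv <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  s <- matrix(stats::rnorm(3 * n), n, 3)
  s <- s / sqrt(rowSums(s^2))
  surf <- sweep(s %*% half_inv, 2, center, "+")
  sqrt(min(rowSums(sweep(surf, 2, as.numeric(p))^2)))
}
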