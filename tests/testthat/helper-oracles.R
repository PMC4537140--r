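# Independent oracles used to validate the analytical implementations.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws:
# the first K elements of 1..N are the annotated ones.
hyper_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0L) return(0)
  combs <- utils::combn(N, n)
  overlaps <- colSums(combs <= K)
  mean(overlaps >= k)
}

# Two-sided Fisher p by direct enumeration over margin-fixed tables with
# exact point probabilities from choose().
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b
  col1 <- a + c
  N <- a + b + c + d
  supp <- max(0, row1 + col1 - N):min(row1, col1)
  pr <- choose(col1, supp) * choose(N - col1, row1 - supp) / choose(N, row1)
  obs <- pr[supp == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Set-formula binary distance |A xor B| / |A or B| from explicit sets.
set_distance_oracle <- function(A, B) {
  u <- union(A, B)
  if (length(u) == 0L) return(0)
  length(setdiff(u, intersect(A, B))) / length(u)
}

# Naive O(n^3) UPGMA: the distance between two clusters is recomputed at
# every step as the mean of all original leaf-pair distances, with the same
# lexicographic tie-break as the implementation.
upgma_oracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    bestval <- Inf
    bestkey <- NULL
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        val <- mean(d[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))),
                     collapse = "\r")
        if (val < bestval - 1e-12 ||
            (abs(val - bestval) <= 1e-12 && key < bestkey)) {
          bestval <- val
          bestkey <- key
          best <- c(i, j)
        }
      }
    }
    newm <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    members[[length(members) + 1L]] <- newm
    heights <- c(heights, bestval)
    clusters <- c(clusters[-best], list(newm))
  }
  list(heights = heights, members = members)
}

# Random sparse 0/1 gene-by-study matrix with no all-zero rows.
random_binary_matrix <- function(G, S, p = 0.3) {
  m <- matrix(rbinom(G * S, 1L, p), G, S,
              dimnames = list(NULL, sprintf("S%d", seq_len(S))))
  for (i in which(rowSums(m) == 0L)) m[i, sample.int(S, 1L)] <- 1L
  m
}
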