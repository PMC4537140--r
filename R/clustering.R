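#' Convert a compendium to a gene-by-study binary matrix
#'
#' Each study becomes a 0/1 column of length equal to the number of
#' compendium genes: 1 where the gene was observed in that study. No row can
#' be all-zero on a valid compendium (every gene is in at least one study).
#'
#' @param compendium A `palm_compendium` data.frame.
#' @return Integer matrix, rownames = gene symbols, colnames = study ids.
#' @export
to_binary_matrix <- function(compendium) {
  study_cols <- grep("^study_", names(compendium), value = TRUE)
  .assert(length(study_cols) > 0L && nrow(compendium) > 0L,
          "validation error: compendium is empty or has no study columns")
  m <- as.matrix(compendium[, study_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- compendium$gene_symbol
  colnames(m) <- sub("^study_", "", study_cols)
  .assert(all(rowSums(m) > 0L),
          "integrity error: compendium gene with no study flag")
  m
}

#' Asymmetric binary (Jaccard) distance between study columns
#'
#' For two 0/1 columns the distance is the number of discordant positions
#' over the number of positions where at least one column is 1 (rows where
#' both are 0 are ignored): `d = |A xor B| / |A or B|`, the distance
#' convention of `dist(..., method = "binary")`. Identical columns give 0;
#' disjoint non-empty columns give 1. A pair of all-zero columns (impossible
#' on a valid compendium) is defined as distance 0 with a warning.
#'
#' @param matrix Gene-by-study 0/1 matrix with at least two columns.
#' @return Symmetric distance matrix over studies (zero diagonal).
#' @examples
#' m <- cbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
#' binary_distance(m)  # 2 discordant / 4 in union = 0.5
#' @export
binary_distance <- function(matrix) {
  .assert(is.matrix(matrix) && ncol(matrix) >= 2L,
          "validation error: need a matrix with >= 2 study columns")
  .assert(all(matrix %in% c(0L, 1L)),
          "validation error: matrix cells must be 0 or 1")
  d <- .binary_distance_fast(matrix, warn = TRUE)
  d
}

#' @noRd
.binary_distance_fast <- function(m, warn = FALSE) {
  storage.mode(m) <- "double"
  both <- crossprod(m)              # |A and B|
  n1 <- diag(both)
  un <- outer(n1, n1, "+") - both   # |A or B|
  d <- (un - both) / un             # |A xor B| / |A or B|
  zero <- un == 0
  if (any(zero)) {
    if (warn) warning("all-zero column pair: distance defined as 0",
                      call. = FALSE)
    d[zero] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Repeatedly merges the pair of clusters with the smallest average
#' inter-cluster distance; the merge height is that average. Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member). Average linkage is
#' monotone, so heights are non-decreasing from leaves to root.
#'
#' @param dist Symmetric distance matrix with zero diagonal and labelled
#'   rows/columns (at least two).
#' @return Object of class `palm_dendro`: list with `labels`, `heights`,
#'   `members` (list of sorted member vectors, one per internal node, in
#'   merge order) and an `hclust`-style `merge` matrix. Convert with
#'   [as.hclust()] or serialise with [to_newick()].
#' @export
average_linkage <- function(dist) {
  .assert(is.matrix(dist) && nrow(dist) == ncol(dist) && nrow(dist) >= 2L,
          "validation error: need a square distance matrix over >= 2 items")
  .assert(max(abs(dist - t(dist))) < 1e-12,
          "validation error: distance matrix must be symmetric")
  .assert(all(dist >= 0) && all(abs(diag(dist)) < 1e-12),
          "validation error: distances must be non-negative with zero diagonal")
  labels <- rownames(dist) %||% paste0("S", seq_len(nrow(dist)))
  n <- nrow(dist)
  D <- dist
  dimnames(D) <- NULL
  members <- as.list(labels)          # current cluster member sets
  ids <- -seq_len(n)                  # hclust convention: leaves negative
  sizes <- rep(1L, n)
  active <- rep(TRUE, n + 0L)
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  node_members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    Dm <- D[act, act, drop = FALSE]
    diag(Dm) <- Inf
    mval <- min(Dm)
    cand <- which(Dm <= mval + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # Tie-break: smallest (first label, second label) pair, labels being the
    # smallest member of each cluster, pair sorted.
    keyify <- function(i, j) {
      a <- min(members[[act[i]]]); b <- min(members[[act[j]]])
      if (a <= b) c(a, b) else c(b, a)
    }
    best <- 1L
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(r) paste(keyify(r[1L], r[2L]),
                                                collapse = "\r"))
      best <- order(keys, method = "radix")[1L]
    }
    i <- act[cand[best, 1L]]
    j <- act[cand[best, 2L]]
    new_members <- sort_c(c(members[[i]], members[[j]]))
    heights[step] <- D[i, j]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    node_members[[step]] <- new_members
    # Average-linkage update: size-weighted mean of the two old distances.
    other <- setdiff(act, c(i, j))
    if (length(other)) {
      D[i, other] <- (sizes[i] * D[i, other] + sizes[j] * D[j, other]) /
        (sizes[i] + sizes[j])
      D[other, i] <- D[i, other]
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- step
    active[j] <- FALSE
  }
  out <- list(labels = labels, merge = merge, heights = heights,
              members = node_members)
  class(out) <- "palm_dendro"
  out
}

#' @export
print.palm_dendro <- function(x, ...) {
  cat(sprintf("Average-linkage dendrogram over %d studies (root height %.4f)\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}

#' @export
as.hclust.palm_dendro <- function(x, ...) {
  n <- length(x$labels)
  ord_of <- function(node) {       # leaf order by recursive descent
    if (node < 0L) return(-node)
    c(ord_of(x$merge[node, 1L]), ord_of(x$merge[node, 2L]))
  }
  structure(list(merge = x$merge, height = x$heights,
                 order = ord_of(n - 1L), labels = x$labels,
                 method = "average", dist.method = "binary"),
            class = "hclust")
}

# Member-set signatures (sorted labels joined by "|") for the internal nodes
# of an hclust tree; used to match clades across bootstrap replicates.
#' @noRd
.hclust_signatures <- function(merge, labels) {
  n <- nrow(merge) + 1L
  mem <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    get <- function(id) if (id < 0L) labels[-id] else mem[[id]]
    mem[[k]] <- c(get(merge[k, 1L]), get(merge[k, 2L]))
  }
  vapply(mem, function(m) paste(sort_c(m), collapse = "|"), "")
}

#' Multiscale bootstrap support for a study dendrogram
#'
#' Resamples genes (rows) with replacement at several scale factors, each
#' time reclustering the studies and recording, per internal node of the
#' reference tree, whether the node's exact member set reappears. The
#' bootstrap probability BP of a node is its appearance fraction at scale 1.
#' The approximately-unbiased (AU) p-value is estimated from the multiscale
#' profile: the normal-quantile transform of `1 - BP_r` is fitted by
#' weighted least squares to `v * sqrt(r) + c / sqrt(r)` (signed distance
#' `v`, curvature `c`), and `AU = 1 - pnorm(v - c)`. AU is reported as `NA`
#' (undefined, not 0) for nodes whose profile leaves fewer than two
#' informative scales, and as 1 for clades recovered in every replicate at
#' every scale.
#'
#' @param matrix Gene-by-study 0/1 matrix the tree was built from.
#' @param tree The [average_linkage()] dendrogram of `matrix`.
#' @param n_samplings Bootstrap replicates per scale (default 5000, the
#'   convention for publication-grade support values; values below 100
#'   trigger a warning).
#' @param scales Row-resampling scale factors; must include 1.
#' @param seed Integer seed; fixed seed makes BP/AU exactly reproducible.
#' @return Object of class `bootstrap_support`: data.frame with one row per
#'   internal node (`node`, `members`, `bp`, `au`, `n_samplings`, `seed`)
#'   and attributes `scales` and `bp_by_scale` (node-by-scale BP matrix).
#' @export
bootstrap_support <- function(matrix, tree, n_samplings = 5000L,
                              scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  .assert(inherits(tree, "palm_dendro"),
          "validation error: tree must come from average_linkage()")
  .assert(all(sort(colnames(matrix)) == sort(tree$labels)),
          "validation error: tree labels do not match matrix columns")
  .assert(any(abs(scales - 1) < 1e-9),
          "validation error: scales must include 1")
  if (n_samplings < 100L) {
    warning("fewer than 100 bootstrap samplings: support values will be noisy",
            call. = FALSE)
  }
  sigs <- vapply(tree$members, paste, "", collapse = "|")
  G <- nrow(matrix)
  labels <- colnames(matrix)
  set.seed(seed)
  counts <- base::matrix(0L, length(sigs), length(scales))
  for (si in seq_along(scales)) {
    m_r <- max(2L, as.integer(round(scales[si] * G)))
    for (b in seq_len(n_samplings)) {
      rows <- sample.int(G, m_r, replace = TRUE)
      db <- .binary_distance_fast(matrix[rows, , drop = FALSE])
      hc <- stats::hclust(stats::as.dist(db), method = "average")
      ss <- .hclust_signatures(hc$merge, labels)
      counts[, si] <- counts[, si] + (sigs %in% ss)
    }
  }
  bp_mat <- counts / n_samplings
  dimnames(bp_mat) <- list(sigs, paste0("r", scales))
  i1 <- which(abs(scales - 1) < 1e-9)[1L]
  au <- vapply(seq_along(sigs), function(i)
    .au_fit(bp_mat[i, ], scales, n_samplings), 0)
  out <- data.frame(node = seq_along(sigs), members = sigs,
                    bp = bp_mat[, i1], au = au,
                    n_samplings = n_samplings, seed = seed,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("bootstrap_support", "data.frame")
  attr(out, "scales") <- scales
  attr(out, "bp_by_scale") <- bp_mat
  out
}

# Two-parameter multiscale-bootstrap fit for one node: weighted least
# squares of qnorm(1 - bp_r) on (sqrt(r), 1/sqrt(r)).
#' @noRd
.au_fit <- function(bps, scales, nb) {
  use <- bps > 0 & bps < 1
  if (!any(use)) {
    if (all(bps == 1)) return(1)     # clade certain at every scale
    return(NA_real_)                 # never re-formed: AU undefined
  }
  if (sum(use) < 2L) return(NA_real_)
  z <- qnorm(1 - bps[use])
  r <- scales[use]
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- nb * dnorm(z)^2 / (bps[use] * (1 - bps[use]))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[[1L]]
  cc <- fit$coefficients[[2L]]
  unname(1 - pnorm(v - cc))
}

#' Serialise a dendrogram to Newick with support-value node labels
#'
#' Converts the dendrogram through [ape::as.phylo()] and attaches
#' `BP/AU` node labels matched by clade member sets, then writes with
#' [ape::write.tree()].
#'
#' @param tree A `palm_dendro` object.
#' @param support Optional [bootstrap_support()] result.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
to_newick <- function(tree, support = NULL, path = NULL) {
  phy <- ape::as.phylo(as.hclust.palm_dendro(tree))
  if (!is.null(support)) {
    parts <- ape::prop.part(phy)
    plab <- attr(parts, "labels")
    sig <- vapply(parts, function(p) paste(sort_c(plab[p]), collapse = "|"),
                  "")
    i <- match(sig, support$members)
    phy$node.label <- ifelse(is.na(i), "",
                             sprintf("%.3f/%s", support$bp[i],
                                     ifelse(is.na(support$au[i]), "NA",
                                            sprintf("%.3f", support$au[i]))))
  }
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
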