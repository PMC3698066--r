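# Alignment-free feature frequency profiles, neighbor-joining trees,
# bootstrap majority-rule consensus, Matching Splits distance and the
# genealogical sorting index.

#' Feature frequency profile of a sequence
#'
#' Sliding-window exact word counts at feature length `L` (default 20
#' bases, suited to genome-scale alignment-free comparison). Windows
#' containing a non-ACGT character are skipped and the total reduced
#' accordingly.
#'
#' @param s nucleotide [seq_record] or string, length >= `L`.
#' @param L feature length.
#' @return Object of class `ffp_profile`: `id`, `L`, `counts` (named integer
#'   vector over observed features), `total`.
#' @export
ffp_profile <- function(s, L = 20) {
  str <- .as_residues(s)
  id <- if (inherits(s, "seq_record")) s$id else "seq"
  n <- nchar(str)
  if (n < L) stop("sequence shorter than feature length L = ", L)
  words <- seq_words(str, L)
  clean <- !grepl("[^ACGT]", words)
  tab <- table(words[clean])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(id = id, L = as.integer(L), counts = counts,
                 total = sum(counts)),
            class = "ffp_profile")
}

#' @export
print.ffp_profile <- function(x, ...) {
  cat(sprintf("<ffp_profile> %s: L=%d, %d distinct features, total %d\n",
              x$id, x$L, length(x$counts), x$total))
  invisible(x)
}

# Jensen-Shannon divergence between two named count/frequency vectors
.jsd <- function(ca, cb) {
  pa <- ca / sum(ca)
  pb <- cb / sum(cb)
  feats <- union(names(pa), names(pb))
  a <- setNames(numeric(length(feats)), feats)
  b <- a
  a[names(pa)] <- pa
  b[names(pb)] <- pb
  m <- (a + b) / 2
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / q[nz]))
  }
  (kl(a, m) + kl(b, m)) / 2
}

#' Jensen-Shannon divergence between two feature profiles
#'
#' Symmetric, bounded divergence (`0 <= d <= ln 2`, natural logarithm)
#' between the normalised profiles; 0 iff the normalised profiles are
#' identical, `ln 2` when the feature sets are disjoint.
#'
#' @param p,q [ffp_profile()] objects with equal `L`.
#' @return Numeric divergence.
#' @export
ffp_distance <- function(p, q) {
  if (p$L != q$L) stop("feature lengths differ: ", p$L, " vs ", q$L)
  .jsd(p$counts, q$counts)
}

#' Pairwise distance matrix from feature profiles
#'
#' @param profiles list of [ffp_profile()] with equal `L`.
#' @return Symmetric matrix with zero diagonal, labelled by profile ids.
#' @export
ffp_dist <- function(profiles) {
  ids <- vapply(profiles, `[[`, "", "id")
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- ffp_distance(profiles[[i]], profiles[[j]])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param D symmetric matrix (zero diagonal) or `dist`, >= 3 labels.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (nrow(D) < 3) stop("need >= 3 labels")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Star tree over a leaf set
#'
#' Single internal node, no internal splits; the fully unresolved reference
#' used to normalise the Matching Splits distance.
#'
#' @param labels leaf labels.
#' @return `phylo` tree.
#' @export
star_tree <- function(labels) {
  ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
}

# non-trivial splits of a tree as a logical matrix (rows = splits, columns =
# leaves in `labels` order); canonicalised so the first leaf is FALSE
tree_splits <- function(tree, labels = sort(tree$tip.label)) {
  if (!setequal(tree$tip.label, labels)) stop("leaf set mismatch")
  sp <- phangorn::as.splits(tree)
  m <- as.matrix(sp)
  m <- m[, labels, drop = FALSE] > 0
  sz <- rowSums(m)
  n <- length(labels)
  keep <- sz >= 2 & sz <= n - 2
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(m)
  flip <- m[, 1]
  m[flip, ] <- !m[flip, , drop = FALSE]
  m[!duplicated(m), , drop = FALSE]
}

# Hungarian algorithm (potentials / shortest augmenting path), square cost
# matrix, returns minimum total assignment cost
hungarian_min_cost <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(0)
  if (n != ncol(cost)) stop("cost matrix must be square")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  total <- 0
  for (j in seq_len(n)) if (p[j + 1] > 0) total <- total + cost[p[j + 1], j]
  total
}

#' Matching Splits distance between two trees
#'
#' Minimum-cost perfect matching between the two trees' non-trivial split
#' sets. The cost of matching two splits is the smaller symmetric-difference
#' size over the two possible side pairings; when the trees have different
#' numbers of splits, the smaller set is padded with "dummy" splits whose
#' matching cost is the extra split's smaller side size. The percentage
#' normalisation divides by the distance from the first tree to the star
#' (fully unresolved) tree on the same leaves, so 100% means "as different
#' as an unresolved tree".
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return Named list: `ms` (integer distance), `pct_of_star`.
#' @examples
#' t1 <- ape::read.tree(text = "((a,b),(c,d));")
#' t2 <- ape::read.tree(text = "((a,c),(b,d));")
#' matching_splits(t1, t2)$ms # 2
#' @export
matching_splits <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  labels <- sort(t1$tip.label)
  s1 <- tree_splits(t1, labels)
  s2 <- tree_splits(t2, labels)
  ms <- .ms_value(s1, s2, length(labels))
  star <- .ms_value(s1, matrix(logical(0), 0, length(labels)), length(labels))
  pct <- if (star > 0) 100 * ms / star else if (ms == 0) 0 else NA_real_
  list(ms = ms, pct_of_star = pct)
}

.split_min_side <- function(m, n) pmin(rowSums(m), n - rowSums(m))

.ms_value <- function(s1, s2, n) {
  n1 <- nrow(s1); n2 <- nrow(s2)
  k <- max(n1, n2)
  if (k == 0) return(0)
  cost <- matrix(0, k, k)
  if (n1 && n2) {
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      d <- sum(xor(s1[i, ], s2[j, ]))
      cost[i, j] <- min(d, n - d)
    }
  }
  if (n1 < k) {
    pad <- .split_min_side(s2, n)
    for (j in seq_len(n2)) cost[(n1 + 1):k, j] <- pad[j]
  }
  if (n2 < k) {
    pad <- .split_min_side(s1, n)
    for (i in seq_len(n1)) cost[i, (n2 + 1):k] <- pad[i]
  }
  hungarian_min_cost(cost)
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples the data with replacement, rebuilds a tree per replicate and
#' keeps the splits occurring in more than `p` of replicates; supports are
#' percent occurrence, attached as node labels. For feature profiles the
#' resampling unit is the feature (k-mer type, resampled across the joint
#' feature table); for an alignment it is the column.
#'
#' @param x list of [ffp_profile()] objects, or a named character vector of
#'   equal-length gapped alignment rows.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param builder function from distance matrix to `phylo` (default
#'   [nj_tree()]).
#' @param p retention threshold (default 0.5, majority rule).
#' @return `phylo` consensus tree with `node.label` percent supports.
#' @export
bootstrap_consensus <- function(x, replicates = 100, builder = nj_tree,
                                p = 0.5) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.list(x) && inherits(x[[1]], "ffp_profile")) {
    ids <- vapply(x, `[[`, "", "id")
    feats <- unique(unlist(lapply(x, function(pr) names(pr$counts))))
    F <- matrix(0, nrow = length(feats), ncol = length(x),
                dimnames = list(feats, ids))
    for (k in seq_along(x)) F[names(x[[k]]$counts), k] <- x[[k]]$counts
    sample_dist <- function() {
      idx <- sample.int(nrow(F), nrow(F), replace = TRUE)
      Fb <- F[idx, , drop = FALSE]
      n <- ncol(Fb)
      D <- matrix(0, n, n, dimnames = list(ids, ids))
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        ca <- Fb[, i]; cb <- Fb[, j]
        nz <- ca > 0 | cb > 0
        ca <- ca[nz]; cb <- cb[nz]
        names(ca) <- names(cb) <- seq_along(ca)
        D[i, j] <- D[j, i] <- .jsd(ca[ca > 0], cb[cb > 0])
      }
      D
    }
  } else {
    rows <- x
    ids <- names(rows)
    mat <- do.call(rbind, strsplit(rows, ""))
    rownames(mat) <- ids
    pdist <- function(m) {
      n <- nrow(m)
      D <- matrix(0, n, n, dimnames = list(ids, ids))
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        ok <- m[i, ] != "-" & m[j, ] != "-"
        D[i, j] <- D[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
      }
      D
    }
    sample_dist <- function() pdist(mat[, sample.int(ncol(mat), ncol(mat),
                                                     replace = TRUE),
                                       drop = FALSE])
  }
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) trees[[r]] <- builder(sample_dist())
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = max(p, 0.5 + 1e-9))
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- round(100 * counts / replicates, 1)
  cons
}

#' Genealogical sorting index of a labelled group on a rooted tree
#'
#' Quantifies the degree of exclusive ancestry of a group of leaves, from 0
#' (maximally dispersed) to 1 (monophyletic). The observed statistic is
#' `(n - 1) / sum(d_u - 1)` over the internal nodes `u` needed to unite the
#' group's leaves up to their most recent common ancestor (`d_u` = number of
#' children), rescaled between its minimum on the tree (all internal nodes
#' involved) and 1.
#'
#' @param tree rooted `phylo` tree.
#' @param group character vector of leaf labels, `2 <= |group| <` leaf count.
#' @return Numeric in `[0, 1]`; 1 iff the group is monophyletic.
#' @export
gsi <- function(tree, group) {
  if (!ape::is.rooted(tree))
    stop("gsi requires a rooted tree (root at an outgroup, or use ",
         "phangorn::midpoint)")
  tips <- tree$tip.label
  if (!all(group %in% tips))
    stop("group label(s) not in tree: ",
         paste(setdiff(group, tips), collapse = ","))
  n <- length(group)
  if (n < 2) stop("group must have >= 2 members")
  if (n >= length(tips)) stop("group must be a proper subset of the leaves")
  tip_idx <- match(group, tips)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nchildren <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  mrca <- ape::getMRCA(tree, group)
  # internal nodes on paths from each group tip up to (and including) the MRCA
  U <- integer(0)
  for (t in tip_idx) {
    v <- parent[t]
    while (TRUE) {
      U <- c(U, v)
      if (v == mrca) break
      v <- parent[v]
    }
  }
  U <- unique(U)
  denom_obs <- sum(nchildren[U] - 1L)
  internal <- which(nchildren > 0)
  denom_all <- sum(nchildren[internal] - 1L)
  gs <- (n - 1) / denom_obs
  gs_min <- (n - 1) / denom_all
  if (gs_min >= 1) return(1)
  (gs - gs_min) / (1 - gs_min)
}

#' Clade recovery report for labelled groups
#'
#' For every cluster and subcluster with at least two members present as
#' leaves: is the group monophyletic on the tree, and what is its [gsi()]?
#' Singleton groups are reported as not applicable (`NA`). Unrooted trees
#' are midpoint-rooted for the evaluation.
#'
#' @param tree `phylo` tree whose leaves are labelled in `labels`.
#' @param labels label table (id, cluster, subcluster).
#' @return `data.frame`: `group`, `level`, `n_members`, `monophyletic`,
#'   `gsi`.
#' @export
clade_recovery <- function(tree, labels) {
  labels <- labels[labels$id %in% tree$tip.label, , drop = FALSE]
  if (nrow(labels) == 0)
    return(data.frame(group = character(0), level = character(0),
                      n_members = integer(0), monophyletic = logical(0),
                      gsi = numeric(0)))
  missing <- setdiff(labels$id, tree$tip.label)
  if (length(missing)) stop("labelled id(s) not in tree")
  rtree <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  groups <- list()
  for (cl in unique(labels$cluster)) {
    groups[[length(groups) + 1]] <-
      list(name = cl, level = "cluster", ids = labels$id[labels$cluster == cl])
  }
  subs <- unique(labels$subcluster[nzchar(labels$subcluster)])
  for (sc in subs) {
    groups[[length(groups) + 1]] <-
      list(name = sc, level = "subcluster",
           ids = labels$id[labels$subcluster == sc])
  }
  out <- lapply(groups, function(g) {
    k <- length(g$ids)
    if (k < 2 || k >= length(rtree$tip.label)) {
      return(data.frame(group = g$name, level = g$level, n_members = k,
                        monophyletic = NA, gsi = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(group = g$name, level = g$level, n_members = k,
               monophyletic = ape::is.monophyletic(rtree, g$ids),
               gsi = gsi(rtree, g$ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
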