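# Neighbor-Joining on gap distances.
#
# The agglomeration is the textbook Saitou-Nei procedure: at each step join
# the pair (i, j) minimising Q(i, j) = (n - 2) d(i, j) - r_i - r_j.  Gap
# distance matrices are full of exact ties (zero blocks are common), so
# determinism matters: among Q-minimal pairs the one whose (lexicographically
# sorted) representative-label pair is smallest is joined, where a cluster is
# represented by its smallest descendant leaf label.  Negative branch-length
# estimates are clamped to zero (downstream clade costs must be
# non-negative); clamps are recorded on the returned tree.

#' Build a Neighbor-Joining tree from a gap-distance matrix
#'
#' @param gdm a `gap_dist` object, or a symmetric numeric matrix with
#'   dimnames.
#' @return an [ape::phylo] tree whose tip labels are the matrix labels; the
#'   tree is unrooted (the final agglomeration leaves a trifurcation).  The
#'   integer attribute `clamped` counts branch estimates clamped to zero.
#'   For a 2-label matrix a single-edge (two half-length branches) tree is
#'   returned.
#' @export
nj_tree <- function(gdm) {
  D <- if (inherits(gdm, "gap_dist")) gdm$d else gdm
  if (!is.matrix(D) || is.null(rownames(D)))
    gc_stop("nj_tree needs a labelled matrix or gap_dist object")
  if (anyNA(D)) gc_stop("distance matrix contains NA/NaN")
  if (max(abs(D - t(D))) > 1e-12) gc_stop("distance matrix is not symmetric")
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2) gc_stop("need at least 2 labels")
  fmt <- function(x) sprintf("%.15g", x)
  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt(D[1, 2] / 2),
                   labels[2], fmt(D[1, 2] / 2))
    tr <- ape::read.tree(text = nwk)
    attr(tr, "clamped") <- 0L
    return(tr)
  }

  newick <- labels          # growing sub-newick per active cluster
  rep_lab <- labels         # smallest descendant leaf label per cluster
  clamped <- 0L
  clamp <- function(x) {
    neg <- x < 0
    clamped <<- clamped + sum(neg)
    x[neg] <- 0
    x
  }

  while (length(rep_lab) > 3) {
    m <- length(rep_lab)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol & upper.tri(Q), arr.ind = TRUE)
    # deterministic tie-break: smallest sorted representative-label pair
    a <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    b <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    lens <- clamp(c(li, lj))
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(lens[1]),
                       newick[j], fmt(lens[2]))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newick <- c(newick[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
  }

  # final three clusters join at an unresolved (trifurcating) node
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(la),
                 newick[2], fmt(lb), newick[3], fmt(lc))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

#' Enumerate the clades of a tree
#'
#' Yields every internal node together with its descendant leaf set, in
#' preorder from the traversal root (the final agglomeration node), so the
#' full leaf set comes first and the order is deterministic for a given
#' tree.
#'
#' @param tree an [ape::phylo] object.
#' @return list of `list(node = internal node id, leaves = character vector
#'   of tip labels)`; empty for a tree with fewer than 2 tips.
#' @export
clades_of <- function(tree) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) < 2) return(list())
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])

  tipsets <- vector("list", ntip + tree$Nnode)
  fill <- function(node) {
    if (node <= ntip) {
      tipsets[[node]] <<- tree$tip.label[node]
    } else {
      for (ch in children[[as.character(node)]]) fill(ch)
      tipsets[[node]] <<- sort(unlist(tipsets[children[[as.character(node)]]]))
    }
  }
  out <- list()
  preorder <- function(node) {
    if (node <= ntip) return()
    out[[length(out) + 1L]] <<- list(node = node, leaves = tipsets[[node]])
    for (ch in children[[as.character(node)]]) preorder(ch)
  }
  fill(root)
  preorder(root)
  out
}
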