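# Tree utilities: support parsing/collapsing, Robinson-Foulds distances,
# representative-topology selection, and a distance-based tree builder.

#' Read a Newick tree with internal-node support labels
#'
#' Internal-node labels are interpreted as bootstrap-style supports on the
#' edge above the node. Supports given on the 0-1 scale (all numeric labels
#' at most 1) are rescaled to 0-100 with a warning.
#'
#' @param path Newick file.
#' @return A `phylo` object.
#' @export
read_support_tree <- function(path) {
  tree <- ape::read.tree(path)
  sup <- node_supports(tree)
  vals <- sup[!is.na(sup)]
  if (length(vals) > 0 && all(vals <= 1) && any(vals > 0)) {
    warn("supports look like proportions; rescaling to 0-100")
    tree$node.label <- ifelse(is.na(sup), tree$node.label, sup * 100)
  }
  tree
}

# Numeric supports per internal node (NA when absent/non-numeric).
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support is less than or equal to
#' `threshold` (inclusive, so support exactly at the threshold is
#' collapsed). The tip set and tip branch lengths are unchanged; the length
#' of a contracted edge is discarded. Edges without a numeric support (the
#' root included) are kept.
#'
#' @param tree A `phylo` with supports in `node.label`.
#' @param threshold Collapse supports `<= threshold` (default 20).
#' @return A `phylo`, possibly multifurcating. The number of edges collapsed
#'   is recorded in `attr(, "n_collapsed")`.
#' @export
collapse_low_support <- function(tree, threshold = 20) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  sup <- node_supports(tree)
  # internal nodes (other than the root) whose subtending edge collapses
  collapse <- which(!is.na(sup) & sup <= threshold) + n_tip
  collapse <- setdiff(collapse, root)
  if (length(collapse) == 0) {
    attr(tree, "n_collapsed") <- 0L
    return(tree)
  }

  labels <- tree$node.label
  lens <- tree$edge.length
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # descend() renders a subtree; edges to collapsed children are spliced
  # into the current level (handles runs of nested collapsed nodes)
  descend <- function(node) {
    if (node <= n_tip) return(gsub("[ ,:;()]", "_", tree$tip.label[node]))
    parts <- character(0)
    stack_edges <- children[[as.character(node)]]
    while (length(stack_edges) > 0) {
      e <- stack_edges[1]; stack_edges <- stack_edges[-1]
      child <- tree$edge[e, 2]
      if (child %in% collapse) {
        stack_edges <- c(children[[as.character(child)]], stack_edges)
      } else {
        parts <- c(parts, paste0(descend(child), ":", format_len(lens[e])))
      }
    }
    paste0("(", paste(parts, collapse = ","), ")", label_of(node))
  }
  label_of <- function(node) {
    if (is.null(labels)) return("")
    lab <- labels[node - n_tip]
    if (is.na(lab) || lab == "") "" else lab
  }
  format_len <- function(x) {
    if (is.null(x) || is.na(x)) "0" else format(x, digits = 15, scientific = FALSE)
  }
  newick <- paste0(descend(root), ";")
  out <- ape::read.tree(text = newick)
  attr(out, "n_collapsed") <- length(collapse)
  out
}

# Canonical non-trivial bipartitions of a tree in the unrooted sense.
# Each split is the sorted tip-label set on the side not containing the
# alphabetically first tip, pasted into a key string.
bipartition_set <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 4) return(character(0))
  anchor <- min(tree$tip.label)
  desc <- tip_descendants(tree)
  keys <- character(0)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    side <- tree$tip.label[desc[[node]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n_tip - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# Tip indices below every node.
tip_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Robinson-Foulds distance between two trees
#'
#' The unweighted, unrooted Robinson-Foulds distance: the size of the
#' symmetric difference of the two trees' non-trivial bipartition sets.
#' Rooted inputs are compared as unrooted topologies.
#'
#' @param t1,t2 `phylo` objects over the same tip set.
#' @return Integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    only1 <- setdiff(t1$tip.label, t2$tip.label)
    only2 <- setdiff(t2$tip.label, t1$tip.label)
    stop_invalid(paste0(
      "trees have different tip sets; only in first: [",
      paste(only1, collapse = ", "), "]; only in second: [",
      paste(only2, collapse = ", "), "]"
    ), class = "phyloskim_tip_mismatch")
  }
  b1 <- bipartition_set(t1)
  b2 <- bipartition_set(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Pick the representative topology of a set of trees
#'
#' Returns the (1-based) index of the tree minimizing the sum of
#' Robinson-Foulds distances to all the others, the standard criterion for
#' choosing one topology to present among near-equivalent analyses. Ties are
#' broken by the lowest index.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`) sharing one
#'   tip set.
#' @return Integer index into `trees`.
#' @export
select_representative <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0) stop_invalid("empty tree list")
  if (length(trees) == 1) return(1L)
  n <- length(trees)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- robinson_foulds(trees[[i]], trees[[j]])
    }
  }
  which.min(rowSums(d))[1]
}

#' Pairwise p-distances with pairwise deletion
#'
#' For each pair of samples, the proportion of differing residues over the
#' columns where neither sequence is `N`. Ambiguity codes are compared as
#' their own symbols.
#'
#' @param aln A `snp_supermatrix` or residue matrix.
#' @return A `dist` object.
#' @export
p_distance <- function(aln) {
  m <- as_residue_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      if (!any(ok)) {
        abort(sprintf(
          "samples %s and %s share no called column; cannot compute a distance",
          rownames(m)[i], rownames(m)[j]
        ), class = c("phyloskim_insufficient_overlap", "phyloskim_error"))
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  stats::as.dist(d)
}

#' Neighbour-joining tree from an alignment
#'
#' Builds a neighbour-joining tree from pairwise-deletion p-distances, a
#' desk-scale topology estimator for filtered SNP supermatrices. The result
#' is deterministic given the alignment.
#'
#' @param aln A `snp_supermatrix` or residue matrix with at least 3 samples.
#' @return An unrooted `phylo`.
#' @export
nj_from_alignment <- function(aln) {
  m <- as_residue_matrix(aln)
  if (nrow(m) < 3) stop_invalid("need at least 3 samples")
  ape::nj(p_distance(m))
}
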