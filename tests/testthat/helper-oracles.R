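# Independent oracles and programmatic fixtures shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Matrix-exponential oracle, independent of the package's transition-matrix
# code (closed form / ape::matexpo).
expm_oracle <- function(M) {
  unname(as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE))))
}

# Exhaustive-enumeration likelihood and marginal oracle: sums the joint
# probability over every assignment of states to internal nodes. Only
# feasible for small trees; deliberately shares no code with the pruning
# implementation.
brute_mk <- function(tree, states, model) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  k <- model$k
  if (is.matrix(states)) {
    tipm <- states[tips, , drop = FALSE]
  } else {
    tipm <- matrix(0, n_tip, k, dimnames = list(tips, model$states))
    v <- states[tips]
    for (i in seq_len(n_tip)) {
      if (is.na(v[i])) tipm[i, ] <- 1
      else tipm[i, match(v[i], model$states)] <- 1
    }
  }
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1):n_node
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) expm_oracle(model$Q * tree$edge.length[e]))
  probs <- model$root_prior[combos[, 1]] # internal[1] is the root
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    par_states <- combos[, par - n_tip]
    if (ch <= n_tip) {
      w <- as.vector(P[[e]] %*% tipm[ch, ])
      probs <- probs * w[par_states]
    } else {
      probs <- probs * P[[e]][cbind(par_states, combos[, ch - n_tip])]
    }
  }
  lik <- sum(probs)
  marg <- t(vapply(
    seq_along(internal),
    function(i) vapply(seq_len(k),
                       function(s) sum(probs[combos[, i] == s]),
                       numeric(1)) / lik,
    numeric(k)
  ))
  rownames(marg) <- as.character(internal)
  colnames(marg) <- model$states
  list(loglik = log(lik), marginals = marg)
}

# --- toy variant tables ------------------------------------------------

# Build a full-grid variant table from per-locus specs. Each locus is
# list(gene, pos, ref, alt, gt = named overrides, dp = named overrides,
# gq = named overrides, absent = sample names, default_gt).
toy_table <- function(samples, loci) {
  rows <- lapply(loci, function(L) {
    gt <- rep(L$default_gt %||% "0/0", length(samples))
    names(gt) <- samples
    if (!is.null(L$gt)) gt[names(L$gt)] <- L$gt
    dp <- rep(10L, length(samples)); names(dp) <- samples
    if (!is.null(L$dp)) dp[names(L$dp)] <- L$dp
    gq <- rep(99, length(samples)); names(gq) <- samples
    if (!is.null(L$gq)) gq[names(L$gq)] <- L$gq
    if (!is.null(L$absent)) gt[L$absent] <- NA
    dp[is.na(gt)] <- NA
    gq[is.na(gt)] <- NA
    tibble::tibble(
      sample = samples, gene = L$gene, pos = L$pos,
      ref = L$ref %||% "A", alt = L$alt %||% "G",
      gt = unname(gt), dp = unname(dp), gq = unname(gq)
    )
  })
  variant_table(dplyr::bind_rows(rows))
}

# The 10-sample x 20-locus hand-counted cascade fixture. Expected outcomes
# (hand arithmetic):
#   per-sample medians: 10 for every sample (locus g2:10 sits at occupancy
#     0.5, not > 0.5, so it never enters the median set)
#   coverage/quality (window [5, 20], quality >= 20): removes 4 calls
#     (g1:1 s03 dp 4, s04 dp 21, s05 dp 1; g1:2 s01 gq 19); no locus drops
#   biallelic: drops g1:3 (three alleles), g1:4 (monomorphic ref),
#     g1:8 (monomorphic alt) -> 17 loci
#   sharing (minor copies >= 3): drops g1:6 (2 copies), g1:9 (ref minor,
#     2 copies) -> 15 loci
#   missing fractions of survivors: g1:1 = 0.3, g1:2 = 0.1, g2:10 = 0.5,
#     the remaining 12 loci = 0
cascade_toy <- function() {
  samples <- sprintf("s%02d", 1:10)
  het3 <- c(s01 = "0/1", s02 = "0/1", s03 = "0/1")
  vanilla <- function(gene, pos) list(gene = gene, pos = pos, gt = het3)
  loci <- list(
    list(gene = "g1", pos = 1L,
         gt = c(s01 = "0/1", s02 = "0/1", s06 = "0/1"),
         dp = c(s01 = 5L, s02 = 20L, s03 = 4L, s04 = 21L, s05 = 1L)),
    list(gene = "g1", pos = 2L,
         gt = c(s02 = "0/1", s03 = "0/1", s04 = "0/1"),
         gq = c(s01 = 19, s02 = 20)),
    list(gene = "g1", pos = 3L, alt = "G,T",
         gt = c(s01 = "1/1", s02 = "1/1", s03 = "1/1",
                s04 = "2/2", s05 = "2/2", s06 = "2/2")),
    list(gene = "g1", pos = 4L),
    list(gene = "g1", pos = 5L, alt = "G,T",
         gt = c(s01 = "0/1", s02 = "0/1", s03 = "0/1", s04 = "0/1")),
    list(gene = "g1", pos = 6L, gt = c(s01 = "0/1", s02 = "0/1")),
    list(gene = "g1", pos = 7L, gt = het3),
    list(gene = "g1", pos = 8L, default_gt = "1/1"),
    list(gene = "g1", pos = 9L, default_gt = "1/1",
         gt = c(s01 = "0/1", s02 = "0/1")),
    vanilla("g1", 10L),
    vanilla("g2", 1L), vanilla("g2", 2L), vanilla("g2", 3L),
    vanilla("g2", 4L), vanilla("g2", 5L), vanilla("g2", 6L),
    vanilla("g2", 7L), vanilla("g2", 8L), vanilla("g2", 9L),
    list(gene = "g2", pos = 10L, gt = het3,
         absent = c("s06", "s07", "s08", "s09", "s10"))
  )
  toy_table(samples, loci)
}

# Alignment whose columns are clade indicators of a tree: every non-trivial
# split contributes `per_split` columns (clade = G, rest = A). p-distances
# on such an alignment form an additive split metric on the tree.
indicator_alignment <- function(tree, per_split = 5) {
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  cols <- list()
  for (node in (n_tip + 2):(n_tip + tree$Nnode)) {
    clade <- desc[[node]]
    if (length(clade) >= 2 && length(clade) <= n_tip - 2) {
      col <- rep("A", n_tip)
      col[clade] <- "G"
      cols <- c(cols, replicate(per_split, col, simplify = FALSE))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- tree$tip.label
  m
}

# Expand a multiPhylo into a plain list of phylo objects (the [[ method
# reinstates the compressed shared tip labels).
as_tree_list <- function(trees) lapply(seq_along(trees), function(i) trees[[i]])

all_unrooted_trees <- function(n) {
  as_tree_list(phangorn::allTrees(n, rooted = FALSE,
                                  tip.label = letters[seq_len(n)]))
}

# All rooted binary topologies on n tips with reproducible branch lengths.
all_rooted_trees <- function(n, seed = 1) {
  trees <- as_tree_list(phangorn::allTrees(n, rooted = TRUE,
                                           tip.label = letters[seq_len(n)]))
  withr::with_seed(seed, {
    lapply(trees, function(tr) {
      tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
      tr
    })
  })
}
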