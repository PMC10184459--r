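#' Simulate a pure-birth species tree
#'
#' Generates a rooted binary tree under a Yule (pure-birth) process with the
#' given per-lineage speciation rate. Branch lengths are in the process's
#' time units, which the variant simulator treats as expected-substitution
#' units. The same seed always yields the same tree.
#'
#' @param n_tips Number of terminal taxa (>= 2).
#' @param birth_rate Per-lineage speciation rate (> 0).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param tip_prefix Prefix for tip labels (`t01`, `t02`, ...).
#' @return An [ape::rphylo()]-style `phylo` object with `n_tips` labelled
#'   tips and strictly positive branch lengths.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL, tip_prefix = "t") {
  if (!is.numeric(n_tips) || length(n_tips) != 1 || n_tips < 2 || n_tips != round(n_tips)) {
    stop_invalid("n_tips must be a single integer >= 2")
  }
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop_invalid("birth_rate must be > 0")
  }
  tree <- with_seed_if(seed, ape::rphylo(as.integer(n_tips), birth = birth_rate, death = 0))
  width <- max(2, nchar(as.character(n_tips)))
  tree$tip.label <- sprintf(paste0(tip_prefix, "%0", width, "d"), seq_len(n_tips))
  tree
}

#' Simulate a diploid biallelic SNP genotype table on a tree
#'
#' Emulates the structure of a reference-based genotype caller's output on
#' genome-skimming data. Each variable site arises once on a uniformly chosen
#' edge of the tree (infinite-sites style): tips below that edge carry the
#' alternate allele, as heterozygotes when the mutation falls on their own
#' terminal edge (a recent mutation) and as alternate homozygotes otherwise.
#' Present calls carry a negative-binomial read depth around a per-sample
#' expected depth and a phred-like quality score; calls are dropped at a
#' per-call missing probability with per-sample and per-gene logit-normal
#' heterogeneity, calibrated so the overall missing fraction equals
#' `missing_rate` in expectation.
#'
#' @param tree A `phylo` tree with uniquely named tips.
#' @param n_loci Number of gene regions.
#' @param sites_per_locus Number of variable sites per gene.
#' @param depth_median Expected per-sample read depth (genome-skimming scale).
#' @param depth_dispersion Negative-binomial overdispersion (size = 1/dispersion).
#' @param missing_rate Marginal probability that a call is absent (0 <= r < 1).
#' @param qual_mean,qual_sd Mean and sd of the phred-like call quality.
#' @param sample_logit_sd,gene_logit_sd Standard deviations of per-sample and
#'   per-gene missingness effects on the logit scale; set both to 0 for
#'   homogeneous missingness.
#' @param seed Optional integer seed.
#' @return A list with `variants` (a [variant_table()] tibble) and `truth`
#'   (the tree plus a tibble of true genotypes and mutation edges per site).
#' @export
simulate_variants <- function(tree, n_loci, sites_per_locus,
                              depth_median = 4, depth_dispersion = 0.5,
                              missing_rate = 0.365,
                              qual_mean = 35, qual_sd = 10,
                              sample_logit_sd = 1, gene_logit_sd = 0.8,
                              seed = NULL) {
  if (anyDuplicated(tree$tip.label)) stop_invalid("tree tips must be uniquely named")
  if (n_loci < 1 || sites_per_locus < 1) stop_invalid("counts must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop_invalid("missing_rate must be in [0, 1)")
  if (depth_median <= 0) stop_invalid("depth_median must be > 0")

  with_seed_if(seed, {
    samples <- tree$tip.label
    n_samp <- length(samples)
    n_tip <- length(tree$tip.label)
    n_edge <- nrow(tree$edge)
    genes <- sprintf("g%03d", seq_len(n_loci))

    # tips descending from each edge (clade below the edge's child node)
    desc <- vector("list", n_tip + tree$Nnode)
    post <- ape::reorder.phylo(tree, "postorder")
    for (i in seq_len(n_tip)) desc[[i]] <- i
    for (e in seq_len(nrow(post$edge))) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    clades <- lapply(seq_len(n_edge), function(e) desc[[tree$edge[e, 2]]])
    terminal <- tree$edge[, 2] <= n_tip

    n_sites <- n_loci * sites_per_locus
    site_gene <- rep(genes, each = sites_per_locus)
    site_pos <- as.integer(replicate(n_loci, sort(sample.int(500L, sites_per_locus))))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    site_edge <- sample.int(n_edge, n_sites, replace = TRUE)

    # genotype matrix: samples x sites, allele-index strings
    gt <- matrix("0/0", nrow = n_samp, ncol = n_sites,
                 dimnames = list(samples, NULL))
    for (s in seq_len(n_sites)) {
      e <- site_edge[s]
      carriers <- clades[[e]]
      gt[carriers, s] <- if (terminal[e]) "0/1" else "1/1"
    }

    # per-sample expected depth; truncated negative-binomial call depth
    mu_s <- depth_median * exp(rnorm(n_samp, 0, 0.3) - 0.3^2 / 2)
    dp <- matrix(
      pmax(1L, rnbinom(n_samp * n_sites,
                       mu = rep(mu_s, times = n_sites),
                       size = 1 / depth_dispersion)),
      nrow = n_samp
    )
    gq <- matrix(
      pmin(99, pmax(1, round(rnorm(n_samp * n_sites, qual_mean, qual_sd)))),
      nrow = n_samp
    )

    # calibrated heterogeneous missingness
    if (missing_rate > 0) {
      u_s <- rnorm(n_samp, 0, sample_logit_sd)
      v_g <- rnorm(n_loci, 0, gene_logit_sd)
      v_site <- rep(v_g, each = sites_per_locus)
      eff <- outer(u_s, v_site, "+")
      cal <- uniroot(
        function(c0) mean(plogis(c0 + eff)) - missing_rate,
        lower = -30, upper = 30, tol = 1e-10
      )$root
      p_miss <- plogis(cal + eff)
      absent <- matrix(rbinom(n_samp * n_sites, 1, as.vector(p_miss)) == 1,
                       nrow = n_samp)
    } else {
      absent <- matrix(FALSE, nrow = n_samp, ncol = n_sites)
    }

    truth <- tibble(
      gene = site_gene, pos = site_pos, ref = ref, alt = alt,
      edge = site_edge,
      n_carriers = vapply(site_edge, function(e) length(clades[[e]]), integer(1))
    )

    long <- tibble(
      sample = rep(samples, times = n_sites),
      gene = rep(site_gene, each = n_samp),
      pos = rep(site_pos, each = n_samp),
      ref = rep(ref, each = n_samp),
      alt = rep(alt, each = n_samp),
      gt = as.vector(gt),
      dp = as.integer(as.vector(dp)),
      gq = as.numeric(as.vector(gq))
    )
    truth_gt <- long |>
      select("sample", "gene", "pos", true_gt = "gt")
    long$gt[as.vector(absent)] <- NA_character_
    long$dp[is.na(long$gt)] <- NA_integer_
    long$gq[is.na(long$gt)] <- NA_real_

    list(
      variants = variant_table(long),
      truth = list(tree = tree, sites = truth, genotypes = truth_gt)
    )
  })
}

#' Simulate a discrete character on a tree under an Mk model
#'
#' Draws a root state from the model's root prior and evolves it along each
#' edge with transition probabilities `P(t) = exp(Qt)`. True internal-node
#' states are recorded so ancestral-state reconstructions can be scored
#' against the truth.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model An [mk_model()].
#' @param seed Optional integer seed.
#' @param n Number of independent replicate characters to simulate.
#' @return A list with `tip_states` and `node_states`: named character
#'   vectors for `n = 1`, otherwise matrices with one column per replicate.
#' @export
simulate_character <- function(tree, model, seed = NULL, n = 1) {
  stopifnot(inherits(model, "mk_model"))
  if (model$k < 2) stop_invalid("model must have k >= 2 states")
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")

  with_seed_if(seed, {
    k <- model$k
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    root <- n_tip + 1L
    pre <- ape::reorder.phylo(tree, "cladewise")

    states_idx <- matrix(NA_integer_, nrow = n_node, ncol = n)
    states_idx[root, ] <- sample.int(k, n, replace = TRUE, prob = model$root_prior)
    # unique edge lengths share a transition matrix
    for (e in seq_len(nrow(pre$edge))) {
      parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
      P <- mk_transition_matrix(model, pre$edge.length[e])
      probs <- P[states_idx[parent, ], , drop = FALSE]
      cp <- probs %*% upper.tri(diag(k), diag = TRUE)
      u <- runif(n)
      states_idx[child, ] <- as.integer(rowSums(u > cp) + 1L)
    }

    lab <- model$states
    tips <- matrix(lab[states_idx[seq_len(n_tip), , drop = FALSE]],
                   nrow = n_tip, dimnames = list(tree$tip.label, NULL))
    nodes <- matrix(lab[states_idx[(n_tip + 1):n_node, , drop = FALSE]],
                    nrow = tree$Nnode,
                    dimnames = list(as.character((n_tip + 1):n_node), NULL))
    if (n == 1) {
      list(tip_states = setNames(tips[, 1], rownames(tips)),
           node_states = setNames(nodes[, 1], rownames(nodes)))
    } else {
      list(tip_states = tips, node_states = nodes)
    }
  })
}
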