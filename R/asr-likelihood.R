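# Felsenstein pruning likelihood, marginal ancestral states and rate
# fitting for Mk models. Polytomies are handled directly by the pruning
# recursion; no arbitrary resolution is introduced.

# Coerce tip states to an indicator matrix (tips x states). Accepts a named
# character vector (NA = unknown), a tibble/data.frame with columns
# taxon/state, or a ready indicator matrix (rows = tips) for polymorphic
# coding. Unknown tips get a row of ones.
tip_state_matrix <- function(tree, states, model) {
  tips <- tree$tip.label
  k <- model$k
  if (is.matrix(states)) {
    missing <- setdiff(tips, rownames(states))
    if (length(missing) > 0) {
      stop_invalid(paste0("tip(s) absent from states: ",
                          paste(missing, collapse = ", ")),
                   class = "phyloskim_missing_taxon")
    }
    m <- states[tips, , drop = FALSE]
    if (ncol(m) != k) stop_invalid("indicator matrix must have k columns")
    return(m * 1)
  }
  if (is.data.frame(states)) {
    cols <- intersect(c("taxon", "state"), names(states))
    if (length(cols) < 2) stop_invalid("data-frame states need columns taxon, state")
    states <- setNames(states$state, states$taxon)
  }
  missing <- setdiff(tips, names(states))
  if (length(missing) > 0) {
    stop_invalid(paste0("tip(s) absent from states: ",
                        paste(missing, collapse = ", ")),
                 class = "phyloskim_missing_taxon")
  }
  v <- states[tips]
  unknown_state <- !is.na(v) & !(v %in% model$states)
  if (any(unknown_state)) {
    stop_invalid(paste0("state(s) outside the model alphabet: ",
                        paste(unique(v[unknown_state]), collapse = ", ")))
  }
  m <- matrix(0, nrow = length(tips), ncol = k,
              dimnames = list(tips, model$states))
  known <- !is.na(v)
  m[cbind(which(known), match(v[known], model$states))] <- 1
  m[!known, ] <- 1
  m
}

# Pruning pass. Returns per-node scaled conditional likelihoods (node x k),
# per-node accumulated log scaling factors, the per-edge transition
# matrices, and the total log-likelihood.
prune_likelihood <- function(tree, states, model) {
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  k <- model$k

  tipm <- tip_state_matrix(tree, states, model)
  L <- matrix(1, nrow = n_node, ncol = k)
  L[seq_len(n_tip), ] <- tipm
  logscale <- numeric(n_node)

  post <- ape::reorder.phylo(tree, "postorder")
  P_edges <- lapply(post$edge.length, function(t) mk_transition_matrix(model, t))
  for (e in seq_len(nrow(post$edge))) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    contrib <- as.vector(P_edges[[e]] %*% L[child, ])
    L[parent, ] <- L[parent, ] * contrib
    logscale[parent] <- logscale[parent] + logscale[child]
    mx <- max(L[parent, ])
    if (mx <= 0) {
      return(list(loglik = -Inf, L = L, logscale = logscale,
                  post = post, P_edges = P_edges))
    }
    # rescale once per incoming edge to avoid underflow on large trees
    L[parent, ] <- L[parent, ] / mx
    logscale[parent] <- logscale[parent] + log(mx)
  }
  loglik <- log(sum(model$root_prior * L[root, ])) + logscale[root]
  list(loglik = loglik, L = L, logscale = logscale, post = post,
       P_edges = P_edges)
}

#' Log-likelihood of a discrete character on a tree under an Mk model
#'
#' Felsenstein's pruning algorithm: the log of the sum over root states of
#' the root prior times the conditional likelihood of the tip states.
#' Unknown tip states contribute a vector of ones; polytomies are supported.
#'
#' @param tree A `phylo` with branch lengths.
#' @param states Tip states: named character vector (NA = unknown), a
#'   tibble with columns `taxon` and `state`, or a tips-by-states indicator
#'   matrix for polymorphic coding.
#' @param model An [mk_model()].
#' @return The log-likelihood (scalar).
#' @export
mk_loglikelihood <- function(tree, states, model) {
  prune_likelihood(tree, states, model)$loglik
}

#' Marginal ancestral state reconstruction
#'
#' For every internal node, the marginal posterior distribution over states,
#' combining the conditional likelihoods below the node with the information
#' above it under the model's root prior (the standard up-down algorithm).
#' The maximum-probability state per node is reported alongside.
#'
#' @inheritParams mk_loglikelihood
#' @return An `ancestral_reconstruction` object: list with `probabilities`
#'   (internal nodes x states matrix, rows summing to 1), `map_state`
#'   (named character vector of maximum-probability states), `loglik`,
#'   `tree`, `model`.
#' @export
marginal_states <- function(tree, states, model) {
  pr <- prune_likelihood(tree, states, model)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  k <- model$k

  # "above" partial vectors, normalized per node (marginals only need
  # proportionality); preorder = reverse postorder edge sweep
  U <- matrix(NA_real_, nrow = n_node, ncol = k)
  U[root, ] <- model$root_prior
  edges <- pr$post$edge
  children <- split(seq_len(nrow(edges)), edges[, 1])
  for (e in rev(seq_len(nrow(edges)))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    if (child <= n_tip) next
    sibs <- setdiff(children[[as.character(parent)]], e)
    w <- U[parent, ]
    for (e2 in sibs) {
      w <- w * as.vector(pr$P_edges[[e2]] %*% pr$L[edges[e2, 2], ])
    }
    u <- as.vector(t(pr$P_edges[[e]]) %*% w)
    s <- sum(u)
    if (s > 0) u <- u / s
    U[child, ] <- u
  }

  internal <- root:n_node
  probs <- U[internal, , drop = FALSE] * pr$L[internal, , drop = FALSE]
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(as.character(internal), model$states)
  map_state <- setNames(model$states[max.col(probs, ties.method = "first")],
                        rownames(probs))
  structure(
    list(probabilities = probs, map_state = map_state, loglik = pr$loglik,
         tree = tree, model = model),
    class = "ancestral_reconstruction"
  )
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<ancestral_reconstruction> %d internal nodes, %d states, logLik %.4f\n",
    nrow(x$probabilities), x$model$k, x$loglik
  ))
  invisible(x)
}

#' Fit the rate(s) of an Mk model by maximum likelihood
#'
#' Equal-rates models are fitted by bounded one-dimensional optimisation of
#' the log rate over `[1e-8, 1e3]`; all-rates-different models by
#' multivariate quasi-Newton optimisation of the log rates started at
#' `1 / (mean root-to-tip depth)`. When all observed tips share one state
#' the likelihood is maximised at the rate lower bound, which is reported
#' with a boundary warning.
#'
#' @inheritParams mk_loglikelihood
#' @param family `"ER"` or `"ARD"`.
#' @param root_prior Root prior probabilities (default uniform).
#' @param state_labels State alphabet; defaults to the sorted observed
#'   states.
#' @param lower,upper Rate bounds for the optimiser.
#' @return An `mk_fit` object: list with `model` (the fitted [mk_model()]),
#'   `loglik`, `convergence` (`TRUE` when the optimiser converged),
#'   `boundary` (`TRUE` when the estimate sits at a bound), `family`.
#' @export
fit_mk_rate <- function(tree, states, family = c("ER", "ARD"),
                        root_prior = NULL, state_labels = NULL,
                        lower = 1e-8, upper = 1e3) {
  family <- match.arg(family)
  if (is.data.frame(states)) states_vec <- setNames(states$state, states$taxon)
  else if (is.matrix(states)) states_vec <- NULL
  else states_vec <- states
  if (is.null(state_labels)) {
    state_labels <- if (is.matrix(states)) colnames(states)
                    else sort(unique(states_vec[!is.na(states_vec)]))
  }
  k <- length(state_labels)
  if (k < 1) stop_invalid("no observed states")
  if (k < 2) stop_invalid("need at least 2 states in the alphabet")
  make_model <- function(rates) {
    if (family == "ER") {
      mk_model(k, "ER", rate = rates, root_prior = root_prior,
               states = state_labels)
    } else {
      mk_model(k, "ARD", rates = rates, root_prior = root_prior,
               states = state_labels)
    }
  }
  negll <- function(logr) -mk_loglikelihood(tree, states, make_model(exp(logr)))

  monomorphic <- !is.null(states_vec) &&
    dplyr::n_distinct(states_vec[!is.na(states_vec)]) < 2

  if (family == "ER") {
    opt <- optimize(negll, interval = log(c(lower, upper)), tol = 1e-8)
    rate <- exp(opt$minimum)
    boundary <- rate <= lower * (1 + 1e-4) || rate >= upper * (1 - 1e-4)
    if (monomorphic) {
      # flat-to-decreasing likelihood in q: report the lower bound
      rate <- lower
      boundary <- TRUE
    }
    if (boundary) {
      warn("rate estimate at the boundary of the search interval",
           class = "phyloskim_boundary")
    }
    model <- make_model(rate)
    list_out <- list(
      model = model, loglik = mk_loglikelihood(tree, states, model),
      convergence = TRUE, boundary = boundary, family = family
    )
  } else {
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    start <- rep(log(1 / mean(depths)), k * (k - 1))
    opt <- optim(start, negll, method = "L-BFGS-B",
                 lower = log(lower), upper = log(upper),
                 control = list(factr = 1e4))
    rates <- exp(opt$par)
    boundary <- any(rates <= lower * (1 + 1e-4)) || any(rates >= upper * (1 - 1e-4))
    if (boundary) {
      warn("rate estimate at the boundary of the search interval",
           class = "phyloskim_boundary")
    }
    model <- make_model(rates)
    list_out <- list(
      model = model, loglik = -opt$value, convergence = opt$convergence == 0,
      boundary = boundary, family = family
    )
  }
  structure(list_out, class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf(
    "<mk_fit> %s Mk model, k = %d; logLik %.4f%s\n",
    x$family, x$model$k, x$loglik,
    if (x$boundary) " (boundary)" else ""
  ))
  if (x$family == "ER") cat(sprintf("  rate = %.6g\n", x$model$rate))
  invisible(x)
}
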