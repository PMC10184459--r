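#' Construct a k-state Mk model of discrete character evolution
#'
#' A continuous-time Markov model with instantaneous rate matrix `Q` and
#' root prior `pi`. Under the equal-rates (ER) family every off-diagonal
#' entry of `Q` equals `rate`; under all-rates-different (ARD) the
#' off-diagonal entries are supplied row-wise in `rates` (k(k-1) values,
#' reading each row left to right, skipping the diagonal). Rows of `Q` sum
#' to zero by construction; non-negative off-diagonals and a root prior
#' summing to one are enforced.
#'
#' @param k Number of states (>= 2).
#' @param family `"ER"` (equal rates, default) or `"ARD"`.
#' @param rate Scalar ER rate per unit branch length.
#' @param rates Off-diagonal entries for ARD, length `k * (k - 1)`.
#' @param root_prior Probability vector of length `k`; default uniform.
#' @param states State labels; default `LETTERS[1:k]`.
#' @return An `mk_model` object with elements `k`, `family`, `Q`,
#'   `root_prior`, `states`, `rate`.
#' @export
mk_model <- function(k, family = c("ER", "ARD"), rate = 1, rates = NULL,
                     root_prior = NULL, states = NULL) {
  family <- match.arg(family)
  if (!is.numeric(k) || k < 2 || k != round(k)) stop_invalid("k must be an integer >= 2")
  k <- as.integer(k)
  if (is.null(states)) states <- LETTERS[seq_len(k)]
  if (length(states) != k) stop_invalid("states must have length k")
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8) {
    stop_invalid("root_prior must be a length-k probability vector")
  }
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (family == "ER") {
    if (!is.numeric(rate) || length(rate) != 1 || rate < 0) {
      stop_invalid("rate must be a single non-negative number")
    }
    Q[] <- rate
  } else {
    if (is.null(rates) || length(rates) != k * (k - 1)) {
      stop_invalid("ARD models need k*(k-1) off-diagonal rates")
    }
    if (any(rates < 0)) {
      stop_invalid("rate matrix is not stochastic: negative off-diagonal rates",
                   class = "phyloskim_invalid_model")
    }
    pos <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- rates[pos]; pos <- pos + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(
    list(k = k, family = family, Q = Q, root_prior = root_prior,
         states = states, rate = if (family == "ER") rate else NA_real_),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("<mk_model> %s, k = %d states (%s)\n", x$family, x$k,
              paste(x$states, collapse = ", ")))
  print(round(x$Q, 6))
  invisible(x)
}

#' Transition probability matrix of an Mk model
#'
#' Computes `P(t) = exp(Q t)`. For the equal-rates family the closed form
#' is used: `P_ii(t) = 1/k + (1 - 1/k) exp(-k q t)` and
#' `P_ij(t) = 1/k - (1/k) exp(-k q t)`; otherwise the matrix exponential is
#' evaluated numerically.
#'
#' @param model An [mk_model()].
#' @param t Branch length (>= 0).
#' @return A row-stochastic `k x k` matrix.
#' @export
mk_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "mk_model"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop_invalid("branch length t must be a single number >= 0")
  }
  k <- model$k
  if (model$family == "ER") {
    e <- exp(-k * model$rate * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- 1 / k + (1 - 1 / k) * e
  } else {
    P <- mat_exp_ss(model$Q * t)
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- list(model$states, model$states)
  P
}

# Matrix exponential by scaling and squaring with a truncated Taylor
# series: exp(M) = (exp(M/2^s))^(2^s), with M/2^s of small norm so the
# series converges to near machine precision in a few terms.
mat_exp_ss <- function(M) {
  n <- nrow(M)
  nrm <- norm(M, "1")
  s <- if (nrm > 0.25) ceiling(log2(nrm / 0.25)) else 0L
  A <- M / 2^s
  out <- diag(n)
  term <- diag(n)
  for (i in 1:24) {
    term <- term %*% A / i
    out <- out + term
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}
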