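# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy an Mk model fit
#'
#' @param x An `mk_fit` from [fit_mk_rate()].
#' @param ... Unused.
#' @return A tibble with one row per estimated rate (`term`, `estimate`).
#' @export
#' @exportS3Method generics::tidy
tidy.mk_fit <- function(x, ...) {
  if (x$family == "ER") {
    tibble(term = "rate", estimate = x$model$rate)
  } else {
    Q <- x$model$Q
    idx <- which(row(Q) != col(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    tibble(
      term = sprintf("rate_%s_to_%s",
                     x$model$states[idx[, 1]], x$model$states[idx[, 2]]),
      estimate = Q[idx]
    )
  }
}

#' Glance at an Mk model fit
#'
#' @inheritParams tidy.mk_fit
#' @return A one-row tibble: `logLik`, `k`, `family`, `convergence`,
#'   `boundary`.
#' @export
#' @exportS3Method generics::glance
glance.mk_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, k = x$model$k, family = x$family,
    convergence = x$convergence, boundary = x$boundary
  )
}

#' Tidy an ancestral reconstruction
#'
#' @param x An `ancestral_reconstruction` from [marginal_states()].
#' @param ... Unused.
#' @return A long tibble: `node`, `state`, `probability`, `map_state`.
#' @export
#' @exportS3Method generics::tidy
tidy.ancestral_reconstruction <- function(x, ...) {
  p <- x$probabilities
  tibble(
    node = rep(as.integer(rownames(p)), times = ncol(p)),
    state = rep(colnames(p), each = nrow(p)),
    probability = as.vector(p)
  ) |>
    mutate(map_state = unname(x$map_state[as.character(.data$node)])) |>
    arrange(.data$node, .data$state)
}

#' Glance at an ancestral reconstruction
#'
#' @inheritParams tidy.ancestral_reconstruction
#' @return A one-row tibble: `logLik`, `n_nodes`, `k`.
#' @export
#' @exportS3Method generics::glance
glance.ancestral_reconstruction <- function(x, ...) {
  tibble(logLik = x$loglik, n_nodes = nrow(x$probabilities), k = x$model$k)
}

#' Plot a missing-data gradient scan
#'
#' Bar chart of retained-locus counts against the missing-data threshold.
#'
#' @param scan A tibble from [missing_gradient_scan()].
#' @return A ggplot object.
#' @export
plot_missing_gradient <- function(scan) {
  ggplot(scan, aes(x = factor(.data$threshold), y = .data$n_loci)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "maximum missing data per SNP (%)",
      y = "SNPs retained",
      title = "Missing-data gradient scan"
    ) +
    theme_minimal()
}

#' @describeIn plot_missing_gradient autoplot method for gradient tibbles is
#'   not registered; use `plot_missing_gradient()` directly.
#' @param object An `ancestral_reconstruction`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ancestral_reconstruction <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = factor(.data$node), y = .data$probability,
               fill = .data$state)) +
    geom_col() +
    labs(
      x = "internal node", y = "marginal posterior probability",
      title = "Marginal ancestral state reconstruction"
    ) +
    theme_minimal()
}

#' Plot the filter-cascade audit trail
#'
#' Locus counts entering and leaving each filter stage.
#'
#' @param table A filtered `skim_variants` tibble (or its audit tibble).
#' @return A ggplot object.
#' @export
plot_filter_audit <- function(table) {
  audit <- if (is.data.frame(table) && "stage" %in% names(table)) table
           else attr(table, "audit")
  if (is.null(audit)) stop_invalid("no audit trail available")
  audit |>
    mutate(stage = factor(.data$stage, levels = .data$stage)) |>
    tidyr::pivot_longer(c("loci_in", "loci_out"),
                        names_to = "side", values_to = "count") |>
    ggplot(aes(x = .data$stage, y = .data$count, fill = .data$side)) +
    geom_col(position = "dodge") +
    labs(x = "filter stage", y = "loci", title = "SNP filter cascade") +
    theme_minimal()
}
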