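# Morphological character utilities: the six-character scheme used for
# Artemisia, character-matrix validation, leaf-size discretisation and
# state-frequency summaries.

#' The six morphological characters and their state alphabets
#'
#' The character scheme used for the genus *Artemisia* and its allies:
#' pollen type, synflorescence type, capitulum type (floret functional sex
#' arrangement), life form, basal leaf morphology and basal leaf size class.
#'
#' @return A tibble with columns `character` and `states` (list-column of
#'   the allowed state labels).
#' @export
morphological_characters <- function() {
  tibble(
    character = c("pollen_type", "synflorescence_type", "capitulum_type",
                  "life_form", "basal_leaf_morphology", "basal_leaf_size"),
    states = list(
      c("artemisia", "anthemis"),
      c("panicle", "raceme", "corymb"),
      c("type1", "type2", "type3", "type4"),
      c("annual_herb", "perennial_herb", "shrub"),
      c("entire_or_three_lobed", "pinnatisect_lt6", "pinnatisect_ge6"),
      c("small", "medium", "large")
    )
  )
}

#' Validate a taxa-by-character state matrix
#'
#' A long character matrix with one row per (taxon, character) observation.
#' States must belong to the character's declared alphabet (see
#' [morphological_characters()] for the default scheme); `NA` marks an
#' unknown state.
#'
#' @param x A data frame with columns `taxon`, `character`, `state`.
#' @param scheme A tibble like [morphological_characters()]; characters not
#'   listed in the scheme are rejected.
#' @return A validated `character_matrix` tibble.
#' @export
character_matrix <- function(x, scheme = morphological_characters()) {
  required <- c("taxon", "character", "state")
  if (!all(required %in% names(x))) {
    stop_invalid("character matrix needs columns taxon, character, state")
  }
  x <- as_tibble(x)
  unknown_char <- setdiff(unique(x$character), scheme$character)
  if (length(unknown_char) > 0) {
    stop_invalid(paste0("unknown character(s): ",
                        paste(unknown_char, collapse = ", ")))
  }
  for (ch in unique(x$character)) {
    allowed <- scheme$states[[match(ch, scheme$character)]]
    vals <- x$state[x$character == ch]
    bad <- setdiff(vals[!is.na(vals)], allowed)
    if (length(bad) > 0) {
      stop_invalid(sprintf(
        "state(s) outside the alphabet of %s: %s", ch,
        paste(bad, collapse = ", ")
      ))
    }
  }
  if (anyDuplicated(paste(x$taxon, x$character))) {
    stop_invalid("duplicate (taxon, character) rows")
  }
  class(x) <- c("character_matrix", class(x)[!class(x) %in% "character_matrix"])
  x
}

#' Extract one character as a named tip-state vector
#'
#' @param cm A [character_matrix()].
#' @param character Character name.
#' @return Named character vector (taxon -> state, NA = unknown).
#' @export
character_states <- function(cm, character) {
  sub <- cm[cm$character == character, , drop = FALSE]
  if (nrow(sub) == 0) stop_invalid(paste0("no rows for character ", character))
  setNames(sub$state, sub$taxon)
}

#' Discretise leaf size from length and width measurements
#'
#' Leaf area is approximated as `length x width x 3/4` (mm^2) and binned:
#' area below 225 mm^2 is a small leaf, at least 225 and below 2025 mm^2 a
#' medium leaf, and at least 2025 mm^2 a large leaf (lower bounds
#' inclusive).
#'
#' @param length,width Leaf length and width in mm (vectorised, > 0).
#' @return A tibble with columns `length`, `width`, `area` (mm^2) and
#'   `size_class` (factor small/medium/large).
#' @export
classify_leaf <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop_invalid("leaf length and width must be positive")
  }
  area <- length * width * 3 / 4
  size_class <- cut(
    area,
    breaks = c(-Inf, 225, 2025, Inf),
    labels = c("small", "medium", "large"),
    right = FALSE
  )
  tibble(length = length, width = width, area = area, size_class = size_class)
}

#' State frequencies over a set of taxa
#'
#' Proportions of each observed state among taxa with a known state,
#' optionally restricted to a subset (e.g. the ingroup).
#'
#' @param states Named character vector of states (NA = unknown), or a
#'   [character_matrix()] together with `character`.
#' @param taxa Optional subset of taxon names.
#' @param character Character name when `states` is a character matrix.
#' @return A tibble with columns `state`, `n`, `proportion` (summing to 1).
#' @export
summarize_state_frequencies <- function(states, taxa = NULL, character = NULL) {
  if (inherits(states, "character_matrix") || is.data.frame(states)) {
    if (is.null(character)) stop_invalid("supply `character` with a character matrix")
    states <- character_states(character_matrix(as_tibble(states)), character)
  }
  if (!is.null(taxa)) {
    if (length(taxa) == 0) stop_invalid("empty taxon subset")
    missing <- setdiff(taxa, names(states))
    if (length(missing) > 0) {
      stop_invalid(paste0("taxa without states: ", paste(missing, collapse = ", ")))
    }
    states <- states[taxa]
  }
  states <- states[!is.na(states)]
  if (length(states) == 0) stop_invalid("no known states in the subset")
  tab <- sort(table(states), decreasing = TRUE)
  tibble(
    state = names(tab),
    n = as.integer(tab),
    proportion = as.numeric(tab) / sum(tab)
  )
}

#' Write an ancestral reconstruction to CSV and annotated Newick
#'
#' @param recon An [marginal_states()] result.
#' @param csv_path Output CSV (`node`, `state`, `probability`, long form).
#' @param newick_path Optional output Newick with the maximum-probability
#'   state written as the internal-node label.
#' @return `csv_path`, invisibly.
#' @export
write_reconstruction <- function(recon, csv_path, newick_path = NULL) {
  stopifnot(inherits(recon, "ancestral_reconstruction"))
  readr::write_csv(tidy(recon), csv_path)
  if (!is.null(newick_path)) {
    tree <- recon$tree
    tree$node.label <- unname(recon$map_state)
    ape::write.tree(tree, file = newick_path)
  }
  invisible(csv_path)
}
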