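#' Read tabular similarity hits (BLAST outfmt 6)
#'
#' Reads a 12-column tab-separated hit table in the standard outfmt-6 column
#' order (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`). Only the query, subject, e-value and bitscore
#' columns are used downstream.
#'
#' @param path Path to a TSV file without header.
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
read_blast_hits <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 12) {
    stop_invalid(sprintf("expected 12 tab-separated columns, found %d", ncol(raw)))
  }
  evalue <- suppressWarnings(as.numeric(raw[[11]]))
  bitscore <- suppressWarnings(as.numeric(raw[[12]]))
  bad <- which(is.na(evalue) | is.na(bitscore) | evalue < 0)
  if (length(bad) > 0) {
    stop_invalid(sprintf(
      "malformed hit row(s) at line(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ), class = "phyloskim_parse_error")
  }
  tibble(
    query_id = raw[[1]], subject_id = raw[[2]],
    evalue = evalue, bitscore = bitscore
  )
}

# Best surviving hit per query: minimum e-value, ties by highest bitscore,
# then lexicographic subject id. Multiple HSPs per (query, subject) pair are
# first collapsed to their best row.
best_hits <- function(hits, evalue_max) {
  hits |>
    group_by(.data$query_id, .data$subject_id) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    filter(.data$evalue < evalue_max) |>
    group_by(.data$query_id) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$subject_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Select one-to-one orthologue pairs by reciprocal best hit
#'
#' A pair `(a, b)` is reported when `b` is `a`'s best surviving hit in the
#' A-to-B table and `a` is `b`'s best surviving hit in the B-to-A table,
#' after discarding all hits with e-value at or above `evalue_max` (the
#' threshold is strict: a mutual best pair at exactly the threshold is
#' excluded). "Best" means lowest e-value, with ties broken by highest
#' bitscore and then lexicographically smallest subject id. The result is
#' one-to-one by construction.
#'
#' @param hits_ab,hits_ba Hit tibbles as returned by [read_blast_hits()]
#'   (columns `query_id`, `subject_id`, `evalue`, `bitscore`), for the two
#'   search directions.
#' @param evalue_max Strict e-value threshold; hits with
#'   `evalue >= evalue_max` are discarded before best hits are determined.
#' @return A tibble with columns `id_a`, `id_b`, `evalue_ab`, `evalue_ba`,
#'   sorted by `id_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    stop_invalid("evalue_max must be > 0")
  }
  for (h in list(hits_ab, hits_ba)) {
    if (!all(c("query_id", "subject_id", "evalue", "bitscore") %in% names(h))) {
      stop_invalid("hit tables need columns query_id, subject_id, evalue, bitscore")
    }
  }
  ab <- best_hits(as_tibble(hits_ab), evalue_max)
  ba <- best_hits(as_tibble(hits_ba), evalue_max)
  inner_join(
    ab |> select(id_a = "query_id", id_b = "subject_id", evalue_ab = "evalue"),
    ba |> select(id_b = "query_id", id_a = "subject_id", evalue_ba = "evalue"),
    by = c("id_a", "id_b")
  ) |>
    select("id_a", "id_b", "evalue_ab", "evalue_ba") |>
    arrange(.data$id_a)
}
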