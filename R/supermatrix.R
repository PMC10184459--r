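#' Build a concatenated SNP supermatrix
#'
#' Concatenates, one column per retained locus, the genotype calls of a
#' filtered variant table into an alignment of IUPAC nucleotide codes:
#' homozygous calls become the base, heterozygous calls the two-base
#' ambiguity code (A/G = R, C/T = Y, ...), absent calls `N`. A locus is
#' retained when its fraction of absent calls is strictly below
#' `max_missing_percent / 100`. Columns are ordered by gene id and then
#' position, and the gene/position map of every column is kept alongside the
#' residue matrix.
#'
#' @param table A [variant_table()], normally the output of
#'   [filter_cascade()].
#' @param max_missing_percent Maximum percent missing data per SNP (strict;
#'   the workflow's headline value is 80).
#' @return A `snp_supermatrix` object: list with `matrix` (samples x columns
#'   character matrix) and `partition` (tibble of `gene`, `pos`, `column`).
#' @export
build_supermatrix <- function(table, max_missing_percent = 80) {
  samples <- sort(unique(table$sample))
  ls <- locus_summary(table) |>
    filter(.data$missing_fraction < max_missing_percent / 100) |>
    arrange(.data$gene, .data$pos)
  if (nrow(ls) == 0) {
    warn(sprintf(
      "no locus has missing data below %d%%: returning an empty alignment",
      as.integer(max_missing_percent)
    ), class = "phyloskim_empty_alignment")
    m <- matrix(character(0), nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
    return(structure(
      list(matrix = m,
           partition = tibble(gene = character(0), pos = integer(0),
                              column = integer(0))),
      class = "snp_supermatrix",
      max_missing_percent = max_missing_percent
    ))
  }

  kept <- table |>
    inner_join(ls |> select("gene", "pos"), by = c("gene", "pos"))
  al <- gt_allele_matrix(kept$gt)
  base_of <- function(idx, ref, alt) {
    out <- rep(NA_character_, length(idx))
    ok <- !is.na(idx)
    alleles <- mapply(locus_alleles, ref[ok], alt[ok], SIMPLIFY = FALSE)
    out[ok] <- mapply(function(a, i) a[i + 1L], alleles, idx[ok])
    out
  }
  b1 <- base_of(al[, 1], kept$ref, kept$alt)
  b2 <- base_of(al[, 2], kept$ref, kept$alt)
  residue <- rep("N", nrow(kept))
  ok <- !is.na(b1)
  residue[ok] <- iupac_code(b1[ok], b2[ok])

  col_key <- paste(ls$gene, ls$pos)
  col_idx <- match(paste(kept$gene, kept$pos), col_key)
  row_idx <- match(kept$sample, samples)
  m <- matrix("N", nrow = length(samples), ncol = nrow(ls),
              dimnames = list(samples, NULL))
  m[cbind(row_idx, col_idx)] <- residue

  structure(
    list(matrix = m,
         partition = ls |> select("gene", "pos") |>
           mutate(column = dplyr::row_number())),
    class = "snp_supermatrix",
    max_missing_percent = max_missing_percent
  )
}

#' @export
print.snp_supermatrix <- function(x, ...) {
  cat(sprintf(
    "<snp_supermatrix> %d samples x %d columns (%d genes), %.1f%% N\n",
    nrow(x$matrix), ncol(x$matrix),
    dplyr::n_distinct(x$partition$gene),
    if (length(x$matrix) > 0) 100 * mean(x$matrix == "N") else 0
  ))
  invisible(x)
}

#' @export
dim.snp_supermatrix <- function(x) dim(x$matrix)

as_residue_matrix <- function(aln) {
  if (inherits(aln, "snp_supermatrix")) aln$matrix
  else if (is.matrix(aln)) aln
  else stop_invalid("expected a snp_supermatrix or a character matrix")
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct non-`N`
#' states are each present in at least two samples. Ambiguity codes other
#' than `N` count as their own state.
#'
#' @param aln A `snp_supermatrix` or a character residue matrix.
#' @return Integer count of informative columns.
#' @export
count_parsimony_informative <- function(aln) {
  m <- as_residue_matrix(aln)
  if (ncol(m) == 0) return(0L)
  sum(vapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j][m[, j] != "N"])
    sum(tab >= 2) >= 2
  }, logical(1)))
}

#' Extract per-gene SNP alignments
#'
#' Splits a filtered variant table into per-gene residue matrices and emits
#' only genes whose alignment has at least `min_len` columns and whose
#' fraction of samples with at least one present call is at least `min_cov`
#' (both bounds inclusive). Genes are emitted in lexicographic order.
#'
#' @param table A filtered [variant_table()].
#' @param min_len Minimum number of alignment columns per gene (default 150).
#' @param min_cov Minimum fraction of samples covered (default 0.5).
#' @return A named list of `gene_alignment` objects (gene id, residue
#'   matrix, covered samples).
#' @export
extract_gene_alignments <- function(table, min_len = 150, min_cov = 0.5) {
  samples <- sort(unique(table$sample))
  genes <- sort(unique(table$gene))
  out <- list()
  for (g in genes) {
    sub <- table |> filter(.data$gene == g)
    n_cols <- dplyr::n_distinct(paste(sub$gene, sub$pos))
    covered <- sub |>
      group_by(.data$sample) |>
      summarise(has_call = any(!is.na(.data$gt)), .groups = "drop")
    cov <- sum(covered$has_call) / length(samples)
    if (n_cols >= min_len && cov >= min_cov) {
      sm <- build_supermatrix(retag_variants(sub), max_missing_percent = 100 + 1e-9)
      out[[g]] <- structure(
        list(gene = g, matrix = sm$matrix, partition = sm$partition,
             coverage = cov),
        class = "gene_alignment"
      )
    }
  }
  out
}

#' Write an alignment to FASTA
#'
#' @param aln A `snp_supermatrix`, `gene_alignment` or residue matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  m <- if (inherits(aln, "gene_alignment")) aln$matrix else as_residue_matrix(aln)
  lines <- character(2 * nrow(m))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  lines[c(FALSE, TRUE)] <- apply(m, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA alignment into a residue matrix
#'
#' @param path FASTA file of equal-length sequences.
#' @return A character matrix with sample rownames, residues upper-case.
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chars <- lapply(as.character(dna), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1) stop_invalid("sequences differ in length")
  m <- do.call(rbind, chars)
  rownames(m) <- names(dna)
  m
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @inheritParams write_alignment_fasta
#' @export
write_alignment_phylip <- function(aln, path) {
  m <- as_residue_matrix(aln)
  lines <- c(
    sprintf("%d %d", nrow(m), ncol(m)),
    paste(rownames(m), apply(m, 1, paste, collapse = ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One `DNA, gene = start-end` line per gene of a supermatrix.
#'
#' @param aln A `snp_supermatrix`.
#' @param path Output file.
#' @export
write_partition_file <- function(aln, path) {
  stopifnot(inherits(aln, "snp_supermatrix"))
  spans <- aln$partition |>
    group_by(.data$gene) |>
    summarise(start = min(.data$column), end = max(.data$column), .groups = "drop") |>
    arrange(.data$start)
  writeLines(sprintf("DNA, %s = %d-%d", spans$gene, spans$start, spans$end), path)
  invisible(path)
}
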