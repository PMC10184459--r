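# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a root seed. Keeps results
# below 2^31 - 1 so the value is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647L)
}

# Run `expr` under `seed` when provided, otherwise use the current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(msg, class = "phyloskim_invalid_input") {
  abort(msg, class = c(class, "phyloskim_error"))
}

# IUPAC ambiguity code for an unordered pair of bases (AG -> R etc.).
# Homozygous pairs map to the base itself.
iupac_code <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  codes <- c(
    AA = "A", CC = "C", GG = "G", TT = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M"
  )
  out <- unname(codes[key])
  if (anyNA(out)) {
    stop_invalid(paste0(
      "cannot encode base pair(s): ",
      paste(unique(key[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

# Split diploid genotype strings ("0/1", "1|2", ...) into a two-column
# integer matrix of allele indices; NA genotypes give NA rows.
gt_allele_matrix <- function(gt) {
  out <- matrix(NA_integer_, nrow = length(gt), ncol = 2)
  ok <- !is.na(gt)
  if (any(ok)) {
    parts <- stringr::str_split_fixed(gsub("\\|", "/", gt[ok]), "/", 2)
    suppressWarnings({
      out[ok, 1] <- as.integer(parts[, 1])
      out[ok, 2] <- as.integer(parts[, 2])
    })
    bad <- ok
    bad[ok] <- is.na(out[ok, 1]) | is.na(out[ok, 2])
    if (any(bad)) {
      stop_invalid(paste0(
        "malformed genotype string(s): ",
        paste(unique(gt[bad]), collapse = ", ")
      ))
    }
  }
  out
}
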