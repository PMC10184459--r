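# End-to-end orchestration: simulate (or ingest) -> filter -> matrices ->
# trees -> ancestral states, with per-stage counters, file artifacts and a
# reproducible run manifest.

#' Pipeline configuration
#'
#' Collects every stage's tunable settings. Defaults are the workflow's
#' standard constants: 80 percent maximum missing data for the headline
#' supermatrix, gene matrices of at least 150 columns covering at least half
#' the samples, support collapsing at 20, and the filter cascade of
#' [filter_config()].
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Root seed; per-stage streams are derived from it.
#' @param n_tips,birth_rate Tree simulation settings.
#' @param n_loci,sites_per_locus,missing_rate Variant simulation settings
#'   (further generator knobs can be passed via `sim_args`).
#' @param sim_args Named list of extra arguments to [simulate_variants()].
#' @param filter A [filter_config()].
#' @param max_missing_percent Supermatrix threshold (default 80).
#' @param min_len,min_cov Gene-matrix emission rules.
#' @param collapse_threshold Support threshold for branch collapsing.
#' @param asr_k Number of states of the simulated morphological character.
#' @param asr_rate True rate used to simulate the character.
#' @param stages Character vector of stages to run, in order; a subset of
#'   `c("simulate", "filter", "gradient", "supermatrix", "genes", "tree",
#'   "asr")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("phyloskim_run_"),
                            seed = 1L,
                            n_tips = 20, birth_rate = 1,
                            n_loci = 150, sites_per_locus = 10,
                            missing_rate = 0.2,
                            sim_args = list(depth_median = 20,
                                            depth_dispersion = 0.25,
                                            qual_mean = 40, qual_sd = 8,
                                            sample_logit_sd = 0.5,
                                            gene_logit_sd = 0.5),
                            filter = filter_config(),
                            max_missing_percent = 80,
                            min_len = 150, min_cov = 0.5,
                            collapse_threshold = 20,
                            asr_k = 3, asr_rate = 0.5,
                            stages = c("simulate", "filter", "gradient",
                                       "supermatrix", "genes", "tree", "asr")) {
  allowed <- c("simulate", "filter", "gradient", "supermatrix", "genes",
               "tree", "asr")
  bad <- setdiff(stages, allowed)
  if (length(bad) > 0) {
    stop_invalid(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), n_tips = n_tips,
         birth_rate = birth_rate, n_loci = n_loci,
         sites_per_locus = sites_per_locus, missing_rate = missing_rate,
         sim_args = sim_args, filter = filter,
         max_missing_percent = max_missing_percent, min_len = min_len,
         min_cov = min_cov, collapse_threshold = collapse_threshold,
         asr_k = asr_k, asr_rate = asr_rate, stages = stages),
    class = "pipeline_config"
  )
}

#' Run the genome-skimming SNP pipeline end to end
#'
#' Executes the enabled stages in order on synthetic data: tree and variant
#' simulation, the SNP filter cascade, the missing-data gradient scan,
#' supermatrix assembly, gene-matrix extraction, neighbour-joining tree
#' estimation (compared against the true simulated topology), and
#' maximum-likelihood ancestral state reconstruction of a character
#' simulated on the true tree. Every artifact is written under
#' `config$out_dir` and checksummed into the returned manifest; re-running
#' with an identical configuration reproduces identical checksums. A stage
#' whose precondition is not met (e.g. matrices requested on an unfiltered
#' table) fails fast naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: `config`, per-stage `counters`, `files`
#'   (tibble of path and md5), and results (`gradient`, `rf_to_truth`,
#'   `mk_fit`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_on <- function(s) s %in% config$stages
  fail_stage <- function(stage, msg) {
    abort(sprintf("stage '%s' failed: %s", stage, msg),
          class = c("phyloskim_stage_error", "phyloskim_error"))
  }
  counters <- list()
  results <- list()
  paths <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  if (!stage_on("simulate")) {
    fail_stage("simulate", "the desk-scale pipeline runs on synthetic input")
  }
  tree <- simulate_tree(config$n_tips, config$birth_rate,
                        seed = derive_seed(config$seed, 1))
  sim <- do.call(simulate_variants, c(
    list(tree = tree, n_loci = config$n_loci,
         sites_per_locus = config$sites_per_locus,
         missing_rate = config$missing_rate,
         seed = derive_seed(config$seed, 2)),
    config$sim_args
  ))
  variants <- sim$variants
  ape::write.tree(tree, file = out("true_tree.nwk"))
  write_vcf(variants, out("variants.vcf"))
  paths <- c(paths, out("true_tree.nwk"), out("variants.vcf"))
  counters$simulate <- list(
    n_tips = length(tree$tip.label),
    n_loci = n_loci_of(variants),
    missing_fraction = mean(is.na(variants$gt))
  )

  filtered <- NULL
  if (stage_on("filter")) {
    filtered <- filter_cascade(variants, config$filter)
    write_filter_audit(filtered, out("filter_audit.tsv"))
    write_vcf(filtered, out("variants_filtered.vcf"))
    paths <- c(paths, out("filter_audit.tsv"), out("variants_filtered.vcf"))
    counters$filter <- as.list(attr(filtered, "audit"))
  }

  need_filtered <- function(stage) {
    if (is.null(filtered) || !isTRUE(attr(filtered, "filtered"))) {
      fail_stage(stage, "requires the filter stage to have run (unfiltered input)")
    }
    filtered
  }

  if (stage_on("gradient")) {
    tab <- need_filtered("gradient")
    grad <- missing_gradient_scan(tab, config$filter$gradient_thresholds)
    readr::write_csv(grad, out("gradient.csv"))
    paths <- c(paths, out("gradient.csv"))
    results$gradient <- grad
  }

  sm <- NULL
  if (stage_on("supermatrix")) {
    tab <- need_filtered("supermatrix")
    sm <- build_supermatrix(tab, config$max_missing_percent)
    write_alignment_fasta(sm, out("supermatrix.fasta"))
    write_partition_file(sm, out("supermatrix.partitions"))
    paths <- c(paths, out("supermatrix.fasta"), out("supermatrix.partitions"))
    counters$supermatrix <- list(
      width = ncol(sm$matrix),
      parsimony_informative = count_parsimony_informative(sm)
    )
    results$supermatrix <- sm
  }

  if (stage_on("genes")) {
    tab <- need_filtered("genes")
    genes <- extract_gene_alignments(tab, config$min_len, config$min_cov)
    counters$genes <- list(n_emitted = length(genes))
    if (length(genes) > 0) {
      gdir <- out("gene_matrices")
      dir.create(gdir, showWarnings = FALSE)
      for (g in names(genes)) {
        p <- file.path(gdir, paste0(g, ".fasta"))
        write_alignment_fasta(genes[[g]], p)
        paths <- c(paths, p)
      }
    }
    results$gene_alignments <- genes
  }

  if (stage_on("tree")) {
    if (is.null(sm)) fail_stage("tree", "requires the supermatrix stage")
    if (ncol(sm$matrix) == 0) fail_stage("tree", "empty supermatrix")
    nj <- nj_from_alignment(sm)
    ape::write.tree(nj, file = out("nj_tree.nwk"))
    paths <- c(paths, out("nj_tree.nwk"))
    rf <- robinson_foulds(nj, tree)
    counters$tree <- list(rf_to_truth = rf)
    results$nj_tree <- nj
    results$rf_to_truth <- rf
  }

  if (stage_on("asr")) {
    true_model <- mk_model(config$asr_k, "ER", rate = config$asr_rate)
    ch <- simulate_character(tree, true_model,
                             seed = derive_seed(config$seed, 3))
    fit <- fit_mk_rate(tree, ch$tip_states, family = "ER")
    recon <- marginal_states(tree, ch$tip_states, fit$model)
    write_reconstruction(recon, out("asr_probabilities.csv"),
                         out("asr_tree.nwk"))
    paths <- c(paths, out("asr_probabilities.csv"), out("asr_tree.nwk"))
    root_id <- as.character(length(tree$tip.label) + 1L)
    counters$asr <- list(
      fitted_rate = fit$model$rate,
      root_state_recovered =
        unname(recon$map_state[root_id] == ch$node_states[root_id])
    )
    results$mk_fit <- fit
    results$reconstruction <- recon
    results$true_character <- ch
  }

  files <- tibble(
    path = paths,
    md5 = unname(tools::md5sum(paths))
  )
  manifest <- structure(
    list(config = config, counters = counters, files = files,
         timestamp = format(Sys.time(), tz = "UTC"),
         results = results, truth = sim$truth),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(
      seed = config$seed,
      stages = config$stages,
      counters = counters,
      files = setNames(as.list(files$md5), basename(files$path))
    ),
    out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d stage(s), %d file(s) in %s\n",
              length(x$counters), nrow(x$files), x$config$out_dir))
  invisible(x)
}
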