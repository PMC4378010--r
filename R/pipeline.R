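# One-config orchestration: simulate -> gene level -> codon level ->
# metagene, with a manifest recording resolved parameters and file hashes
# so a rerun under the same config is bit-identical.

#' Default pipeline configuration
#'
#' Every tunable analysis constant surfaced as a named parameter with its
#' standard value: window half-width 60 nt, head/tail exclusions 20/10
#' codons, 20 covariate bins, metagene length floor 500 nt, automatic
#' A-site offset calibration.
#'
#' @return Named list; see [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "riboflux_out",
    stages = list(simulate = TRUE, gene_level = TRUE, codon_level = TRUE,
                  metagene = TRUE),
    scenario = list(),        # overrides passed to sim_scenario()
    n_rp = 2e5, n_mrna = 2e5, n_rp_samples = 2L, n_mrna_samples = 2L,
    inputs = list(genes = NULL, genome = NULL, rp = NULL, mrna = NULL),
    params = list(half_width = 60L, exclude_head = 20L, exclude_tail = 10L,
                  n_bins = 20L, min_len = 500L, offset = "auto",
                  min_mrna = 10, sam_delta = 1, sam_permutations = 200L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(config) {
  st <- config$stages
  if (!isTRUE(st$simulate)) {
    if ((isTRUE(st$gene_level) || isTRUE(st$codon_level) || isTRUE(st$metagene)) &&
        (is.null(config$inputs$genes) || is.null(config$inputs$rp))) {
      abort("without the simulate stage, inputs$genes and inputs$rp are required")
    }
    if (isTRUE(st$codon_level) && is.null(config$inputs$genome)) {
      abort("codon_level requires a genome (inputs$genome)")
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages: `simulate` (genome + RP/mRNA read sets with ground truth),
#' `gene_level` (expression table, R/m ratios, CAI bins, SAM selection),
#' `codon_level` (offset calibration, A-site densities, CV profile,
#' isoacceptor pairs, usage) and `metagene`. The configuration is
#' validated before any stage runs; a failing stage leaves the outputs of
#' completed stages in place and reports which stage failed. All outputs
#' plus a `manifest.json` (resolved config, file md5 hashes) are written to
#' `out_dir`.
#'
#' @param config A list (merged over [default_config()]) or the path to a
#'   YAML file of overrides.
#' @return The manifest, invisibly (list with `config`, `files`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    readr::write_tsv(x, p)
    files <<- c(files, p)
    p
  }
  fail <- function(stage, e) {
    abort(sprintf("stage '%s' failed: %s (prior outputs kept)", stage,
                  conditionMessage(e)))
  }
  p <- config$params

  ## --- inputs ------------------------------------------------------------
  rp_sets <- list(); mrna_sets <- list(); genome <- NULL; models <- NULL
  if (isTRUE(config$stages$simulate)) {
    tryCatch({
      scen <- do.call(sim_scenario,
                      merge_config(list(seed = config$seed), config$scenario))
      gen <- build_genome(scen)
      genome <- gen$genome; models <- gen$models
      Biostrings::writeXStringSet(genome, file.path(out, "genome.fa"))
      write_gene_models(models, file.path(out, "genes.bed"), "bed")
      files <- c(files, file.path(out, c("genome.fa", "genes.bed")))
      truth <- NULL
      for (k in seq_len(config$n_rp_samples)) {
        fp <- simulate_footprints(scen, genome, models, config$n_rp,
                                  seed = scen$seed + 1000L * k)
        truth <- fp$truth
        rp_sets[[paste0("rp", k)]] <- fp$records
        write_alignments(fp$records, file.path(out, sprintf("rp%d.tsv", k)))
        files <- c(files, file.path(out, sprintf("rp%d.tsv", k)))
      }
      for (k in seq_len(config$n_mrna_samples)) {
        mr <- simulate_mrna_reads(scen, genome, models, config$n_mrna,
                                  seed = scen$seed + 2000L * k)
        mrna_sets[[paste0("mrna", k)]] <- mr
        write_alignments(mr, file.path(out, sprintf("mrna%d.tsv", k)))
        files <- c(files, file.path(out, sprintf("mrna%d.tsv", k)))
      }
      jsonlite::write_json(list(codon_dwell = as.list(truth$codon_dwell),
                                cut_offset = truth$cut_offset,
                                initiation_rate = as.list(truth$initiation_rate),
                                mrna_abundance = as.list(truth$mrna_abundance)),
                           file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out, "truth.json"))
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      models <- read_gene_models(config$inputs$genes)
      if (!is.null(config$inputs$genome)) {
        genome <- Biostrings::readDNAStringSet(config$inputs$genome)
        names(genome) <- sub("\\s.*$", "", names(genome))
      }
      rp_sets <- lapply(config$inputs$rp, read_alignments)
      names(rp_sets) <- paste0("rp", seq_along(rp_sets))
      if (!is.null(config$inputs$mrna)) {
        mrna_sets <- lapply(config$inputs$mrna, read_alignments)
        names(mrna_sets) <- paste0("mrna", seq_along(mrna_sets))
      }
    }, error = function(e) fail("inputs", e))
  }
  glen <- if (!is.null(genome)) Biostrings::width(genome)[1] else
    max(models$end) + 200L

  ## --- gene level --------------------------------------------------------
  rm_tbl <- NULL; rp_expr <- NULL; mrna_expr <- NULL
  if (isTRUE(config$stages$gene_level)) {
    tryCatch({
      rp_expr <- expression_table(rp_sets, models)
      mrna_expr <- expression_table(mrna_sets, models)
      emit(bind_rows(mutate(rp_expr, assay = "rp"),
                     mutate(mrna_expr, assay = "mrna")), "expression.tsv")
      rm_tbl <- rm_ratio(rp_expr, mrna_expr, min_mrna = p$min_mrna)
      emit(rm_tbl, "rm_ratio.tsv")
      if (!is.null(genome)) {
        cai <- compute_cai(models, genome, cai_reference_from_rp(rp_expr))
        emit(cai, "cai.tsv")
        bins <- quantile_bin_summary(rm_tbl, setNames(cai$cai, cai$gene_id),
                                     n_bins = p$n_bins)
        emit(bins$bins, "bins_cai.tsv")
      }
      if (length(rp_sets) >= 2 && length(mrna_sets) >= 2) {
        sam <- sam_select(rp_expr, mrna_expr, delta = p$sam_delta,
                          n_permutations = p$sam_permutations,
                          seed = config$seed)
        emit(sam$per_gene, "sam.tsv")
      }
    }, error = function(e) fail("gene_level", e))
  }

  ## --- codon level -------------------------------------------------------
  if (isTRUE(config$stages$codon_level)) {
    tryCatch({
      tracks <- lapply(rp_sets, build_depth_track,
                       mode = "three_prime_only", reference_length = glen)
      offset <- if (identical(p$offset, "auto")) {
        calibrate_asite_offset(tracks[[1]], models,
                               min_genes = min(100L, nrow(models)))
      } else as.integer(p$offset)
      mats <- lapply(names(tracks), function(s) {
        rl <- relative_density(tracks[[s]], models, p$half_width,
                               p$exclude_head, p$exclude_tail)
        codon_position_matrix(rl, models, genome, offset,
                              exclude_head = p$exclude_head,
                              exclude_tail = p$exclude_tail, sample_id = s)
      })
      names(mats) <- names(tracks)
      asum <- asite_summary(mats)
      emit(asum$codon, "asite_density.tsv")
      emit(bind_rows(lapply(mats, as_tibble)), "matrix_long.tsv")
      emit(mutate(position_cv_profile(mats), offset = offset), "cv_profile.tsv")
      prs <- isoacceptor_pair_test(asum)
      emit(prs$pairs, "pairs.tsv")
      usage <- synonymous_usage(models, genome, mrna_expr)
      emit(usage, "usage.tsv")
    }, error = function(e) fail("codon_level", e))
  }

  ## --- metagene ----------------------------------------------------------
  if (isTRUE(config$stages$metagene)) {
    tryCatch({
      trk <- build_depth_track(rp_sets[[1]], "three_prime_only", glen)
      prof <- metagene_profile(trk, models, min_len = p$min_len)
      emit(prof, "metagene.tsv")
    }, error = function(e) fail("metagene", e))
  }

  manifest <- list(config = config,
                   files = lapply(setNames(nm = basename(files)), function(f) {
                     unname(tools::md5sum(file.path(out, f)))
                   }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
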