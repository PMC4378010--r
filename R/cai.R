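# Codon adaptation index, Sharp & Li convention: relative adaptiveness
# w = codon frequency in a highly-expressed reference set divided by the
# frequency of the commonest synonymous codon; CAI is the geometric mean of
# w over a gene's codons, excluding the single-codon families (Met ATG,
# Trp TGG) and stops. Zero-count reference codons are floored at 0.5
# occurrences so no w is exactly zero.

# codon counts (named over the 61 sense codons) for a set of genes
codon_counts_for_genes <- function(models, genome, gene_ids = models$gene_id) {
  idx <- match(gene_ids, models$gene_id)
  if (anyNA(idx)) {
    abort(paste0("gene(s) absent from models: ",
                 paste(gene_ids[is.na(idx)], collapse = ", ")))
  }
  sc <- sense_codons()
  counts <- setNames(numeric(nrow(sc)), sc$codon)
  for (i in idx) {
    cds <- gene_sequence(genome, models$reference[i], models$start[i],
                         models$end[i], models$strand[i])
    cdn <- split_codons(cds)
    cdn <- cdn[!(cdn %in% STOP_CODONS)]
    t <- table(cdn)
    t <- t[names(t) %in% sc$codon]
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  counts
}

#' Relative adaptiveness of each codon to a reference gene set
#'
#' @param models,genome Annotation and sequence.
#' @param reference_set Character vector of highly expressed gene ids.
#' @return Tibble `codon`, `aa`, `ref_count`, `w`.
#' @export
relative_adaptiveness <- function(models, genome, reference_set) {
  if (!length(reference_set)) abort("reference_set is empty")
  counts <- codon_counts_for_genes(models, genome, reference_set)
  counts[counts == 0] <- 0.5
  sc <- sense_codons()
  sc$ref_count <- unname(counts[sc$codon])
  sc |>
    group_by(.data$aa) |>
    mutate(w = .data$ref_count / max(.data$ref_count)) |>
    ungroup() |>
    select("codon", "aa", "ref_count", "w")
}

#' Codon adaptation index per gene
#'
#' @param models,genome Annotation and sequence.
#' @param reference_set Gene ids of the highly-expressed reference; every
#'   id must be present in `models`.
#' @return Tibble `gene_id`, `cai` (in (0, 1]); genes not flagged
#'   `codon_eligible` get `NA`.
#' @export
compute_cai <- function(models, genome, reference_set) {
  w_tbl <- relative_adaptiveness(models, genome, reference_set)
  w <- setNames(w_tbl$w, w_tbl$codon)
  single_aa <- w_tbl |> group_by(.data$aa) |> summarise(k = dplyr::n())
  excluded_codons <- w_tbl$codon[w_tbl$aa %in% single_aa$aa[single_aa$k == 1]]
  models <- if ("codon_eligible" %in% names(models)) models else
    flag_codon_eligibility(models)
  cai <- vapply(seq_len(nrow(models)), function(i) {
    if (!models$codon_eligible[i]) return(NA_real_)
    cds <- gene_sequence(genome, models$reference[i], models$start[i],
                         models$end[i], models$strand[i])
    cdn <- split_codons(cds)
    cdn <- cdn[!(cdn %in% c(STOP_CODONS, excluded_codons))]
    if (!length(cdn)) return(NA_real_)
    exp(mean(log(w[cdn])))
  }, numeric(1))
  tibble(gene_id = models$gene_id, cai = cai)
}

#' Default CAI reference set: the most RP-abundant genes
#'
#' The classical reference is "very highly expressed genes"; here the top
#' `fraction` of genes by RP RPKMc.
#'
#' @param rp_expression Long expression tibble ([rpkmc()] format).
#' @param fraction Top fraction to keep (default 0.05).
#' @return Character vector of gene ids.
#' @export
cai_reference_from_rp <- function(rp_expression, fraction = 0.05) {
  means <- rp_expression |>
    group_by(.data$gene_id) |>
    summarise(m = mean(.data$rpkmc), .groups = "drop") |>
    arrange(dplyr::desc(.data$m))
  head(means$gene_id, max(1L, ceiling(nrow(means) * fraction)))
}
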