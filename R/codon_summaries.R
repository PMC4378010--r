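# rank tests on tiny sample sets can degenerate (all-zero differences);
# report NA rather than fail
safe_wilcox <- function(...) {
  tryCatch(suppressWarnings(wilcox.test(...)$p.value),
           error = function(e) NA_real_)
}

# Summaries built on the codon x position density matrices: A-site means
# across samples, synonymous usage, isoacceptor pair contrasts, the
# positional coefficient-of-variation profile, gene-level predicted
# densities and rescaling onto an external decoding-rate scale.

#' A-site density summary across samples
#'
#' Mean and SD over samples of the position-0 (A-site) density of each
#' sense codon, pairwise rank tests between synonymous codons, and
#' within-family renormalized values (family mean set to 1, the form used
#' for usage comparisons).
#'
#' @param matrices Named list of `codon_density_matrix` objects (one per
#'   sample; >= 2 samples required for tests).
#' @return Object of class `asite_summary`: list with `codon` (tibble
#'   `codon`, `aa`, `mean`, `sd`, `norm_mean`), `values` (long per-sample
#'   tibble) and `tests` (pairwise synonymous Wilcoxon results).
#' @export
asite_summary <- function(matrices) {
  if (inherits(matrices, "codon_density_matrix")) matrices <- list(s1 = matrices)
  if (is.null(names(matrices))) names(matrices) <- paste0("s", seq_along(matrices))
  sc <- sense_codons()
  vals <- bind_rows(lapply(names(matrices), function(s) {
    m <- matrices[[s]]
    j <- which(m$positions == 0L)
    tibble(sample_id = s, codon = rownames(m$mean), density = m$mean[, j])
  })) |> left_join(sc[, c("codon", "aa")], by = "codon")
  codon_tbl <- vals |>
    group_by(.data$codon, .data$aa) |>
    summarise(mean = mean(.data$density, na.rm = TRUE),
              sd = if (dplyr::n() > 1) sd(.data$density, na.rm = TRUE) else NA_real_,
              .groups = "drop")
  fam_norm <- vals |>
    group_by(.data$sample_id, .data$aa) |>
    mutate(norm = .data$density / mean(.data$density, na.rm = TRUE)) |>
    group_by(.data$codon) |>
    summarise(norm_mean = mean(.data$norm, na.rm = TRUE), .groups = "drop")
  codon_tbl <- left_join(codon_tbl, fam_norm, by = "codon")
  tests <- NULL
  if (length(matrices) >= 2) {
    fams <- split(sc$codon, sc$aa)
    fams <- fams[vapply(fams, length, integer(1)) >= 2]
    tests <- bind_rows(lapply(names(fams), function(a) {
      cds <- fams[[a]]
      prs <- utils::combn(cds, 2)
      bind_rows(lapply(seq_len(ncol(prs)), function(k) {
        x <- vals$density[vals$codon == prs[1, k]]
        y <- vals$density[vals$codon == prs[2, k]]
        ok <- complete.cases(x, y)
        p <- if (sum(ok) >= 2) safe_wilcox(x[ok], y[ok], paired = TRUE)
        else NA_real_
        tibble(aa = a, codon1 = prs[1, k], codon2 = prs[2, k],
               mean1 = mean(x, na.rm = TRUE), mean2 = mean(y, na.rm = TRUE),
               p_value = p)
      }))
    }))
  }
  structure(list(codon = codon_tbl, values = vals, tests = tests),
            class = "asite_summary")
}

#' @export
print.asite_summary <- function(x, ...) {
  cat(sprintf("<asite_summary> %d codons, %d sample(s)\n",
              nrow(x$codon), length(unique(x$values$sample_id))))
  print(arrange(x$codon, dplyr::desc(.data$mean)), n = 5)
  invisible(x)
}

# per-gene codon count matrix (genes x 61), sense codons only
gene_codon_count_matrix <- function(models, genome,
                                    exclude_head = 0L, exclude_tail = 0L) {
  models <- if ("codon_eligible" %in% names(models)) models else
    flag_codon_eligibility(models)
  sc <- sense_codons()
  mat <- matrix(0L, nrow = nrow(models), ncol = nrow(sc),
                dimnames = list(models$gene_id, sc$codon))
  for (i in seq_len(nrow(models))) {
    if (!models$codon_eligible[i]) next
    cds <- gene_sequence(genome, models$reference[i], models$start[i],
                         models$end[i], models$strand[i])
    cdn <- split_codons(cds)
    n_sense <- length(cdn) - 1L
    keep <- seq_len(n_sense)
    if (exclude_head + exclude_tail > 0) {
      keep <- keep[keep > exclude_head & keep <= n_sense - exclude_tail]
    }
    cdn <- cdn[keep]
    cdn <- cdn[cdn %in% sc$codon]
    if (!length(cdn)) next
    t <- table(cdn)
    mat[i, names(t)] <- as.integer(t)
  }
  mat
}

#' Expression-weighted relative synonymous codon usage
#'
#' Each gene's codon counts are weighted by its mean mRNA RPKMc (so usage
#' reflects the transcript pool, not the genome), summed, and normalized
#' within each amino-acid family to sum to 1.
#'
#' @param models,genome Annotation and sequence.
#' @param mrna_expression Long expression tibble ([rpkmc()] format); `NULL`
#'   weights all genes equally.
#' @return Tibble `codon`, `aa`, `weighted_count`, `usage` (family sums
#'   to 1).
#' @export
synonymous_usage <- function(models, genome, mrna_expression = NULL) {
  mat <- gene_codon_count_matrix(models, genome)
  w <- rep(1, nrow(mat))
  if (!is.null(mrna_expression)) {
    mw <- mrna_expression |>
      group_by(.data$gene_id) |>
      summarise(m = mean(.data$rpkmc), .groups = "drop")
    w <- setNames(mw$m, mw$gene_id)[rownames(mat)]
    w[is.na(w)] <- 0
  }
  totals <- colSums(mat * w)
  sc <- sense_codons()
  tibble(codon = sc$codon, aa = sc$aa, weighted_count = unname(totals[sc$codon])) |>
    group_by(.data$aa) |>
    mutate(usage = if (sum(.data$weighted_count) > 0)
      .data$weighted_count / sum(.data$weighted_count) else NA_real_) |>
    ungroup()
}

#' Default isoacceptor codon pairs
#'
#' Synonymous pairs decoded by a single tRNA via wobble: 11 NNU/NNC pairs
#' read by one GXX-anticodon tRNA and 4 NNA/NNG pairs read by one
#' UXX-anticodon tRNA, following E. coli K-12 anticodon assignments. This
#' table is a curated reconstruction (the membership is not uniquely fixed
#' by the wobble rule alone) and is user-replaceable.
#'
#' @return Tibble `aa`, `codon1`, `codon2`, `pair_class` (`"NNU_NNC"` or
#'   `"NNA_NNG"`); `codon1` is the U- or A-ending member.
#' @export
default_isoacceptor_pairs <- function() {
  tibble(
    aa = c("F", "Y", "C", "H", "N", "D", "S", "I", "G", "A", "V",
           "K", "E", "V", "A"),
    codon1 = c("TTT", "TAT", "TGT", "CAT", "AAT", "GAT", "AGT", "ATT",
               "GGT", "GCT", "GTT", "AAA", "GAA", "GTA", "GCA"),
    codon2 = c("TTC", "TAC", "TGC", "CAC", "AAC", "GAC", "AGC", "ATC",
               "GGC", "GCC", "GTC", "AAG", "GAG", "GTG", "GCG"),
    pair_class = c(rep("NNU_NNC", 11), rep("NNA_NNG", 4))
  )
}

#' Contrast A-site densities within isoacceptor codon pairs
#'
#' For each pair, the per-sample density difference (codon1 - codon2) and
#' a paired rank test across samples; across pairs of each class, a
#' one-sided signed-rank test of whether the U/A-ending member carries
#' higher density than its C/G-ending partner.
#'
#' @param asite An `asite_summary` (its per-sample `values` are used) or a
#'   long tibble `codon`, `sample_id`, `density`.
#' @param pairs Pair table as [default_isoacceptor_pairs()].
#' @return List with `pairs` (per-pair tibble incl. `diff`, `p_value`) and
#'   `class_tests` (per `pair_class` signed-rank over pair differences;
#'   suppressed when a class has a single usable pair).
#' @export
isoacceptor_pair_test <- function(asite, pairs = default_isoacceptor_pairs()) {
  if (!nrow(pairs)) abort("pair table is empty")
  vals <- if (inherits(asite, "asite_summary")) asite$values else as_tibble(asite)
  have <- unique(vals$codon)
  per_pair <- bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    c1 <- pairs$codon1[k]; c2 <- pairs$codon2[k]
    if (!(c1 %in% have) || !(c2 %in% have)) {
      warn(sprintf("pair %s/%s skipped: codon missing from matrix", c1, c2))
      return(NULL)
    }
    x <- vals$density[vals$codon == c1]
    y <- vals$density[vals$codon == c2]
    ok <- complete.cases(x, y)
    p <- if (sum(ok) >= 2) safe_wilcox(x[ok], y[ok], paired = TRUE)
    else NA_real_
    tibble(aa = pairs$aa[k], codon1 = c1, codon2 = c2,
           pair_class = pairs$pair_class[k],
           mean1 = mean(x, na.rm = TRUE), mean2 = mean(y, na.rm = TRUE),
           diff = mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE), p_value = p)
  }))
  class_tests <- per_pair |>
    group_by(.data$pair_class) |>
    summarise(n_pairs = dplyr::n(),
              n_positive = sum(.data$diff > 0),
              p_value = if (dplyr::n() >= 2)
                safe_wilcox(.data$diff, alternative = "greater")
              else NA_real_,
              .groups = "drop")
  list(pairs = per_pair, class_tests = class_tests)
}

#' Coefficient of variation of codon densities at each position
#'
#' CV (SD/mean over the codon means; the scale-free choice) at every
#' relative position, on the count-weighted average of the supplied
#' matrices. Positions where fewer than 3 codons are measurable give `NA`.
#'
#' @param matrices A `codon_density_matrix` or list of them (e.g. one drug
#'   mode's samples).
#' @param statistic `"cv"` (default) or `"sd"`.
#' @return Tibble `position`, `value`, `n_codons`.
#' @export
position_cv_profile <- function(matrices, statistic = c("cv", "sd")) {
  statistic <- match.arg(statistic)
  m <- average_matrices(matrices)
  vals <- vapply(seq_along(m$positions), function(j) {
    v <- m$mean[, j]
    v <- v[!is.na(v)]
    if (length(v) < 3) return(c(NA_real_, length(v)))
    s <- sd(v)
    c(if (statistic == "cv") s / mean(v) else s, length(v))
  }, numeric(2))
  tibble(position = m$positions, value = vals[1, ],
         n_codons = as.integer(vals[2, ]))
}

#' Gene-level ribosome density predicted from codon composition
#'
#' Per gene, the arithmetic mean of its codons' A-site densities (head and
#' tail exclusions applied, matching the density estimation), plus the
#' max/min fold across genes and the central-90% fold (95th/5th percentile
#' ratio). Quantifies how much of the between-gene density range codon
#' composition alone can generate.
#'
#' @param models,genome Annotation and sequence.
#' @param asite_means Named vector of per-codon A-site densities, or the
#'   `codon` tibble of an [asite_summary()].
#' @param exclude_head,exclude_tail Codon exclusions per gene (defaults
#'   20/10).
#' @return List with `genes` (tibble `gene_id`, `predicted_density`),
#'   `max_fold`, `central90_fold`.
#' @export
gene_predicted_density <- function(models, genome, asite_means,
                                   exclude_head = 20L, exclude_tail = 10L) {
  if (is.data.frame(asite_means)) {
    asite_means <- setNames(asite_means$mean, asite_means$codon)
  }
  sc <- sense_codons()
  miss <- setdiff(sc$codon, names(asite_means))
  if (length(miss)) abort(paste0("asite means missing codons: ",
                                 paste(head(miss, 5), collapse = ", ")))
  mat <- gene_codon_count_matrix(models, genome, exclude_head, exclude_tail)
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  dens <- as.vector(mat %*% asite_means[colnames(mat)]) / rowSums(mat)
  genes <- tibble(gene_id = rownames(mat), predicted_density = dens)
  list(genes = genes,
       max_fold = max(dens) / min(dens),
       central90_fold = central_fold_range(dens, 0.90))
}

#' Rescale codon densities onto an external decoding-rate scale
#'
#' Observed relative densities compress the true decoding-rate range (slow
#' codons also shorten the time resolution of the snapshot), so an affine
#' map on `log(1/density)` is chosen to make the min and max of the mapped
#' values equal the min and max of the log external rates over the shared
#' codons. Returns the mapped per-codon rates (and the corresponding
#' adjusted densities `1/rate`), plus gene-level folds when annotation and
#' genome are supplied.
#'
#' @param asite_means Named per-codon densities or an [asite_summary()]
#'   codon tibble.
#' @param external_rates Named per-codon external rates (>= 2 shared
#'   codons).
#' @param models,genome Optional; when given, gene folds are computed via
#'   [gene_predicted_density()] on the adjusted densities.
#' @return List with `codon` (tibble `codon`, `density`, `rescaled_rate`,
#'   `rescaled_density`), `rate_fold` (max/min rescaled rate), and
#'   optionally `gene_folds`.
#' @export
rescale_to_external <- function(asite_means, external_rates,
                                models = NULL, genome = NULL) {
  if (is.data.frame(asite_means)) {
    asite_means <- setNames(asite_means$mean, asite_means$codon)
  }
  shared <- intersect(names(asite_means), names(external_rates))
  if (length(shared) < 2) abort("external table must cover >= 2 shared codons")
  x <- log(1 / asite_means)          # high = fast
  if (diff(range(x[shared])) == 0) abort("degenerate: all densities equal")
  y <- log(external_rates[shared])
  b <- diff(range(y)) / diff(range(x[shared]))
  a <- min(y) - b * min(x[shared])
  rate <- exp(a + b * x)
  out <- tibble(codon = names(asite_means), density = unname(asite_means),
                rescaled_rate = unname(rate),
                rescaled_density = unname(1 / rate))
  res <- list(codon = out, rate_fold = max(rate) / min(rate))
  if (!is.null(models) && !is.null(genome)) {
    res$gene_folds <- gene_predicted_density(
      models, genome, setNames(out$rescaled_density, out$codon))
  }
  res
}

#' Sensitivity of codon densities to poly(A) 3'-end ambiguity
#'
#' A 3'-terminal template A cannot be distinguished from the poly(A) tail
#' added during library construction. This contrasts the A-site density
#' matrix built from all reads with one built only from reads whose
#' 3'-end's downstream-adjacent template base is not A (the unaffected
#' subset), and reports the per-codon discrepancy and its rank correlation
#' with codon usage.
#'
#' @param records Footprint alignment tibble.
#' @param genome,models Sequence and annotation.
#' @param offset A-site to 3'-end offset.
#' @param usage Optional [synonymous_usage()] table (or named counts);
#'   defaults to unweighted genomic codon counts.
#' @param half_width,exclude_head,exclude_tail Passed through to the
#'   density computation.
#' @return List with `matrix_all`, `matrix_filtered`, `per_codon` (tibble
#'   `codon`, `density_all`, `density_filtered`, `discrepancy`, `usage`),
#'   `spearman_rho` (discrepancy vs usage), `n_all`, `n_filtered`.
#' @export
polya_sensitivity <- function(records, genome, models, offset, usage = NULL,
                              half_width = 60L, exclude_head = 20L,
                              exclude_tail = 10L) {
  validate_gene_models(models)
  ref <- unique(records$reference)[1]
  refseq <- as.character(genome[[ref]])
  plus <- records$strand == "+"
  nextpos <- ifelse(plus, records$three_prime + 1L, records$three_prime - 1L)
  inb <- nextpos >= 0L & nextpos < nchar(refseq)
  nb <- rep(NA_character_, nrow(records))
  nb[inb] <- substring(refseq, nextpos[inb] + 1L, nextpos[inb] + 1L)
  nb[inb & !plus] <- chartr("ACGT", "TGCA", nb[inb & !plus])
  keep <- !is.na(nb) & nb != "A"
  if (!any(keep)) {
    warn("all reads end before a template A; filtered set empty")
    return(list(matrix_all = NULL, matrix_filtered = NULL, per_codon = NULL,
                spearman_rho = NA_real_, n_all = nrow(records), n_filtered = 0L))
  }
  glen <- nchar(refseq)
  one_matrix <- function(recs) {
    trk <- build_depth_track(recs, "three_prime_only", glen)
    rl <- relative_density(trk, models, half_width, exclude_head, exclude_tail)
    codon_position_matrix(rl, models, genome, offset,
                          exclude_head = exclude_head,
                          exclude_tail = exclude_tail)
  }
  m_all <- one_matrix(records)
  m_fil <- one_matrix(records[keep, , drop = FALSE])
  j <- which(m_all$positions == 0L)
  per <- tibble(codon = rownames(m_all$mean),
                density_all = m_all$mean[, j],
                density_filtered = m_fil$mean[, j]) |>
    mutate(discrepancy = abs(.data$density_all - .data$density_filtered))
  if (is.null(usage)) {
    cnt <- colSums(gene_codon_count_matrix(models, genome))
    usage <- tibble(codon = names(cnt), usage = unname(cnt))
  } else if (!is.data.frame(usage)) {
    usage <- tibble(codon = names(usage), usage = unname(usage))
  }
  per <- left_join(per, usage[, c("codon", "usage")], by = "codon")
  ok <- complete.cases(per$discrepancy, per$usage)
  rho <- if (sum(ok) >= 3)
    suppressWarnings(cor(per$discrepancy[ok], per$usage[ok], method = "spearman"))
  else NA_real_
  list(matrix_all = m_all, matrix_filtered = m_fil, per_codon = per,
       spearman_rho = rho, n_all = nrow(records), n_filtered = sum(keep))
}
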