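# Gene-averaged depth profiles anchored at the gene 5' end, the initiation
# peak statistics, and operon-scale track export.

#' Metagene depth profile anchored at the gene 5' end
#'
#' Genes strictly longer than `min_len` are selected; each gene's depth
#' over the window (transcript-relative positions, negative = upstream of
#' the start codon) is normalized to its own mean, then averaged across
#' genes, so library-size and per-gene depth differences cancel. Genes
#' whose window crosses a reference edge, or whose window mean is zero, are
#' skipped.
#'
#' @param track A `depth_track` (either mode).
#' @param models Gene-model tibble.
#' @param min_len Minimum gene length in nt, exclusive (default 500).
#' @param window Integer positions relative to the gene 5' end (default
#'   `-20:480`).
#' @return Tibble of class `metagene_profile`: `position`, `mean_depth`,
#'   `n_genes`, with attributes `depth_mode` and `anchor`.
#' @export
metagene_profile <- function(track, models, min_len = 500L, window = -20:480) {
  validate_gene_models(models)
  sel <- which(models$end - models$start > min_len)
  boundary <- which(models$end - models$start == min_len)
  if (length(boundary)) {
    warn(sprintf("%d gene(s) exactly %d nt excluded (strictly-greater rule)",
                 length(boundary), min_len))
  }
  if (!length(sel)) abort("no qualifying genes for the metagene profile")
  mat <- matrix(NA_real_, nrow = length(window), ncol = length(sel))
  used <- 0L
  for (k in seq_along(sel)) {
    i <- sel[k]
    d <- transcript_depth(track, models$start[i], models$end[i],
                          models$strand[i], min(window), max(window))
    if (anyNA(d)) next                      # window crosses a reference edge
    m <- mean(d)
    if (m == 0) next
    mat[, k] <- d / m
    used <- used + 1L
  }
  if (used == 0L) abort("no qualifying genes for the metagene profile")
  if (used < 10L) warn(sprintf("only %d gene(s) contribute to the profile", used))
  out <- tibble(position = window,
                mean_depth = rowMeans(mat, na.rm = TRUE),
                n_genes = used)
  class(out) <- c("metagene_profile", class(out))
  attr(out, "depth_mode") <- track$mode
  attr(out, "anchor") <- "gene_start"
  out
}

#' Initiation peak position and read fraction
#'
#' The initiation peak is the profile argmax over positions < `max_pos`
#' (default +30: in 3'-end coordinates the initiation complex cuts at
#' start + cut offset + 3, ~15 nt, so the search window must reach past
#' it). Its read fraction is
#' computed from raw (unnormalized) 3'-end counts in `peak +/- 1` nt,
#' summed over all genes, divided by all 3'-end counts inside CDS - the
#' quantity behind "the initiation peak accounts for a fraction x of CDS
#' reads".
#'
#' @param profile A [metagene_profile()].
#' @param track The 3'-end `depth_track` the profile was built from
#'   (needed for raw counts; optional, fraction is `NA` without it).
#' @param models Gene-model tibble (required with `track`).
#' @param max_pos Peak search bound (default 30).
#' @return List with `peak_position` and `peak_fraction_of_cds_reads`.
#' @export
start_peak_stats <- function(profile, track = NULL, models = NULL,
                             max_pos = 30L) {
  cand <- profile$position < max_pos
  if (!any(cand)) abort("no profile positions below the search bound")
  if (diff(range(profile$mean_depth)) == 0) abort("flat profile: no peak")
  peak <- profile$position[cand][which.max(profile$mean_depth[cand])]
  frac <- NA_real_
  if (!is.null(track) && !is.null(models)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(models))) {
      Lt <- models$end[i] - models$start[i]
      d <- transcript_depth(track, models$start[i], models$end[i],
                            models$strand[i])
      den <- den + sum(d)
      win <- (peak - 1L):(peak + 1L)
      win <- win[win >= 0L & win < Lt]
      num <- num + sum(d[win + 1L])
    }
    frac <- if (den > 0) num / den else NA_real_
  }
  list(peak_position = as.integer(peak), peak_fraction_of_cds_reads = frac)
}

#' Export normalized RP and mRNA tracks for a genomic region
#'
#' Both tracks are normalized by their sample's mean depth over the total
#' coding region (so "the average depth of the total coding region is 1"),
#' emitted as a long tibble and optionally as a bedGraph pair, together
#' with the R/m ratio of every gene overlapping the region (mean
#' normalized RP depth over mean normalized mRNA depth within the gene).
#'
#' @param rp_track,mrna_track `depth_track`s of the two assays.
#' @param models Gene-model tibble.
#' @param region Length-2 integer vector `c(start, end)`, 0-based
#'   half-open.
#' @param out_dir Optional directory for `rp.bedgraph` / `mrna.bedgraph` /
#'   `genes_rm.tsv`.
#' @return List with `tracks` (tibble `assay`, `strand`, `pos`, `depth`)
#'   and `genes` (tibble `gene_id`, `strand`, `rm_ratio`).
#' @export
region_track_export <- function(rp_track, mrna_track, models, region,
                                out_dir = NULL) {
  stopifnot(length(region) == 2, region[1] < region[2])
  if (region[1] < 0 || region[2] > rp_track$length) {
    abort("region outside the reference")
  }
  cds_mean <- function(track) {
    tot <- 0; n <- 0
    for (i in seq_len(nrow(models))) {
      idx <- (models$start[i] + 1L):models$end[i]
      tot <- tot + sum(track$depth[[models$strand[i]]][idx])
      n <- n + length(idx)
    }
    if (n == 0 || tot == 0) abort("no CDS signal to normalize by")
    tot / n
  }
  norm_rp <- cds_mean(rp_track); norm_mrna <- cds_mean(mrna_track)
  pos <- region[1]:(region[2] - 1L)
  tracks <- bind_rows(lapply(c("+", "-"), function(s) {
    bind_rows(
      tibble(assay = "rp", strand = s, pos = pos,
             depth = rp_track$depth[[s]][pos + 1L] / norm_rp),
      tibble(assay = "mrna", strand = s, pos = pos,
             depth = mrna_track$depth[[s]][pos + 1L] / norm_mrna))
  }))
  inreg <- which(models$start < region[2] & models$end > region[1])
  genes <- bind_rows(lapply(inreg, function(i) {
    dr <- transcript_depth(rp_track, models$start[i], models$end[i],
                           models$strand[i])
    dm <- transcript_depth(mrna_track, models$start[i], models$end[i],
                           models$strand[i])
    mr <- mean(dm) / norm_mrna
    tibble(gene_id = models$gene_id[i], strand = models$strand[i],
           rm_ratio = if (mr > 0) (mean(dr) / norm_rp) / mr else NA_real_)
  }))
  if (is.null(genes)) genes <- tibble(gene_id = character(),
                                      strand = character(),
                                      rm_ratio = numeric())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in c("+", "-")) {
      tag <- if (s == "+") "plus" else "minus"
      write_depth_bedgraph(rp_track, file.path(out_dir, paste0("rp_", tag, ".bedgraph")),
                           norm_rp, s)
      write_depth_bedgraph(mrna_track, file.path(out_dir, paste0("mrna_", tag, ".bedgraph")),
                           norm_mrna, s)
    }
    readr::write_tsv(genes, file.path(out_dir, "genes_rm.tsv"))
  }
  list(tracks = tracks, genes = genes)
}
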