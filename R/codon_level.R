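# Nucleotide-resolution ribosome density. The mapped signal is the
# footprint 3' end, which the nuclease leaves a fixed offset (~12 nt)
# downstream of the first base of the A-site codon. Relative density
# normalizes each position by its own +/-60 nt window, then by per-frame
# factors, so libraries of different depth are directly comparable.

#' Calibrate the A-site to 3'-end offset from a start-anchored metagene
#'
#' Builds the 3'-end depth metagene over the first `window` nt of each
#' qualifying gene. The dominant 5'-terminal peak is the frozen initiation
#' complex, whose start codon occupies the P-site, so the A-site first base
#' is at transcript position 3; the offset is the per-gene peak position
#' minus 3, and the modal value across genes is returned.
#'
#' @param track 3'-end `depth_track` ([build_depth_track()] in
#'   `three_prime_only` mode).
#' @param models Gene-model tibble.
#' @param window Nt of gene 5' end scanned for the peak (default 60).
#' @param min_reads Minimum 3'-end count within the window for a gene to
#'   qualify (default 10).
#' @param min_genes Minimum number of qualifying genes (default 100).
#' @return Integer offset in nt. Errors with "calibration failed" when the
#'   aggregate metagene has no peak above 3x its local background.
#' @export
calibrate_asite_offset <- function(track, models, window = 60L,
                                   min_reads = 10, min_genes = 100) {
  validate_gene_models(models)
  prof <- matrix(NA_real_, nrow = window, ncol = nrow(models))
  offs <- rep(NA_integer_, nrow(models))
  for (i in seq_len(nrow(models))) {
    if (models$end[i] - models$start[i] < window) next
    d <- transcript_depth(track, models$start[i], models$end[i],
                          models$strand[i], 0L, window - 1L)
    if (anyNA(d) || sum(d) < min_reads) next
    offs[i] <- which.max(d) - 1L - 3L
    prof[, i] <- d / mean(d)
  }
  qual <- which(!is.na(offs))
  if (length(qual) < min_genes) {
    abort(sprintf("calibration needs >= %d genes with >= %g reads in the first %d nt (have %d)",
                  min_genes, min_reads, window, length(qual)))
  }
  meta <- rowMeans(prof[, qual, drop = FALSE])
  if (max(meta) < 3 * median(meta)) {
    abort("calibration failed: no peak above 3x local background")
  }
  tab <- table(offs[qual])
  as.integer(names(tab)[which.max(tab)])
}

#' Window- and frame-normalized relative ribosome density per gene
#'
#' Each transcript position's 3'-end depth is divided by the mean depth of
#' the surrounding `2*half_width + 1` nt window (clipped to the transcript;
#' positions with < 50% window coverage, or a zero window mean, are flagged
#' missing, never zero). Because depth differs systematically between the
#' three bases of a codon, per-frame factors - the mean relative density of
#' each frame class over the included codons (head/tail exclusions applied)
#' of all genes - are then divided out. A frame class with no signal gets
#' an `NA` factor and its positions stay missing.
#'
#' @param track 3'-end `depth_track`.
#' @param models Gene-model tibble (codon-ineligible genes skipped).
#' @param half_width Window half width in nt (default 60).
#' @param exclude_head,exclude_tail Codons dropped at the gene 5'/3' ends
#'   when computing the frame factors (defaults 20 and 10, where depth is
#'   systematically inflated).
#' @param min_window_coverage Minimum fraction of the window inside the
#'   transcript (default 0.5).
#' @return Tibble `gene_id`, `tpos` (transcript position), `frame`,
#'   `depth`, `rel` (window-normalized), `rel_norm` (frame-normalized),
#'   `included` (inside the head/tail-excluded codon body), with attribute
#'   `frame_factors` (length-3 numeric).
#' @export
relative_density <- function(track, models, half_width = 60L,
                             exclude_head = 20L, exclude_tail = 10L,
                             min_window_coverage = 0.5) {
  if (half_width < 1) abort("half_width must be >= 1")
  models <- if ("codon_eligible" %in% names(models)) models else
    flag_codon_eligibility(models)
  use <- models[models$codon_eligible, , drop = FALSE]
  parts <- vector("list", nrow(use))
  for (i in seq_len(nrow(use))) {
    Lt <- use$end[i] - use$start[i]
    d <- transcript_depth(track, use$start[i], use$end[i], use$strand[i])
    S <- c(0, cumsum(d))
    pos <- seq_len(Lt) - 1L
    lo <- pmax(0L, pos - half_width)
    hi <- pmin(Lt - 1L, pos + half_width)
    nwin <- hi - lo + 1L
    wmean <- (S[hi + 2L] - S[lo + 1L]) / nwin
    rel <- ifelse(nwin / (2 * half_width + 1) < min_window_coverage |
                    wmean == 0, NA_real_, d / wmean)
    n_sense <- Lt %/% 3L - 1L
    cidx <- pos %/% 3L
    included <- cidx >= exclude_head & cidx <= (n_sense - 1L - exclude_tail) &
      cidx < n_sense
    parts[[i]] <- tibble(gene_id = use$gene_id[i], tpos = pos,
                         frame = pos %% 3L, depth = d, rel = rel,
                         included = included)
  }
  out <- bind_rows(parts)
  ff <- vapply(0:2, function(k) {
    v <- out$rel[out$included & out$frame == k]
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m) || m == 0) NA_real_ else m
  }, numeric(1))
  out$rel_norm <- out$rel / ff[out$frame + 1L]
  attr(out, "frame_factors") <- ff
  out
}

#' Mean relative density of each codon at each position around the A-site
#'
#' Position 0 is the first base of the A-site codon and the 5' direction is
#' negative. A codon occurrence at transcript position `t0` sits at
#' relative position `p` for ribosomes whose A-site is at `t0 - p`, whose
#' footprint 3' ends therefore fall at `t0 - p + offset`; cell
#' `(codon, p)` is the mean frame-normalized relative 3'-end density over
#' those positions, taken over every retained occurrence (the first
#' `exclude_head` and last `exclude_tail` codons of each gene are
#' excluded). Each (position, sample) column is renormalized to
#' count-weighted mean 1 over codons.
#'
#' @param rel Output of [relative_density()].
#' @param models,genome Annotation and sequence.
#' @param offset Calibrated A-site to 3'-end offset
#'   ([calibrate_asite_offset()]).
#' @param positions Relative positions (default `-45:45`).
#' @param exclude_head,exclude_tail Codons dropped per gene (defaults
#'   20/10).
#' @param sample_id Optional label.
#' @return Object of class `codon_density_matrix`: list with `mean` and
#'   `count` (61 x length(positions) matrices, rows = sense codons),
#'   `positions`, `offset`, `sample_id`.
#' @export
codon_position_matrix <- function(rel, models, genome, offset,
                                  positions = -45:45,
                                  exclude_head = 20L, exclude_tail = 10L,
                                  sample_id = NULL) {
  models <- if ("codon_eligible" %in% names(models)) models else
    flag_codon_eligibility(models)
  use <- models[models$codon_eligible, , drop = FALSE]
  sc <- sense_codons()
  nP <- length(positions)
  sums <- matrix(0, nrow = nrow(sc), ncol = nP)
  cnts <- matrix(0L, nrow = nrow(sc), ncol = nP)
  rel_by_gene <- split(rel[, c("tpos", "rel_norm")], rel$gene_id)
  n_used <- 0L
  for (i in seq_len(nrow(use))) {
    g <- use$gene_id[i]
    rg <- rel_by_gene[[g]]
    if (is.null(rg)) next
    Lt <- use$end[i] - use$start[i]
    n_sense <- Lt %/% 3L - 1L
    c_keep <- seq.int(exclude_head, n_sense - 1L - exclude_tail)
    if (exclude_head > n_sense - 1L - exclude_tail) next
    cds <- gene_sequence(genome, use$reference[i], use$start[i], use$end[i],
                         use$strand[i])
    codons <- split_codons(cds)[c_keep + 1L]
    ci <- match(codons, sc$codon)
    ok_c <- !is.na(ci)
    if (!any(ok_c)) next
    v <- rep(NA_real_, Lt)
    v[rg$tpos + 1L] <- rg$rel_norm
    t0 <- 3L * c_keep[ok_c]
    tp <- outer(t0, offset - positions, "+")       # occurrences x positions
    val <- matrix(NA_real_, nrow = nrow(tp), ncol = nP)
    inb <- tp >= 0L & tp < Lt
    val[inb] <- v[tp[inb] + 1L]
    good <- !is.na(val)
    if (!any(good)) next
    rows <- rep(ci[ok_c], times = nP)[good]
    cols <- rep(seq_len(nP), each = sum(ok_c))[good]
    cell <- rows + nrow(sc) * (cols - 1L)
    add_s <- rowsum(val[good], cell)
    add_n <- rowsum(rep(1L, length(cell)), cell)
    at <- as.integer(rownames(add_s))
    sums[at] <- sums[at] + add_s[, 1]
    cnts[at] <- cnts[at] + add_n[, 1]
    n_used <- n_used + 1L
  }
  if (n_used == 0L) abort("no gene long enough for the requested exclusions")
  mean_mat <- sums / ifelse(cnts > 0, cnts, NA_real_)
  # per-position renormalization: count-weighted codon mean exactly 1
  for (j in seq_len(nP)) {
    ok <- !is.na(mean_mat[, j])
    wm <- sum(cnts[ok, j] * mean_mat[ok, j]) / sum(cnts[ok, j])
    if (is.finite(wm) && wm > 0) mean_mat[, j] <- mean_mat[, j] / wm
  }
  dimnames(mean_mat) <- dimnames(cnts) <- list(sc$codon, as.character(positions))
  structure(list(mean = mean_mat, count = cnts, positions = positions,
                 offset = offset, sample_id = sample_id),
            class = "codon_density_matrix")
}

#' @export
print.codon_density_matrix <- function(x, ...) {
  cat(sprintf("<codon_density_matrix> %d codons x %d positions (%d..%d), offset %d%s\n",
              nrow(x$mean), length(x$positions), min(x$positions),
              max(x$positions), x$offset,
              if (is.null(x$sample_id)) "" else paste0(", sample ", x$sample_id)))
  invisible(x)
}

#' Tidy a codon density matrix into long form
#' @param x A `codon_density_matrix`.
#' @param ... Unused.
#' @return Tibble `codon`, `position`, `density`, `count`, `sample_id`.
#' @export
as_tibble.codon_density_matrix <- function(x, ...) {
  tibble(codon = rep(rownames(x$mean), times = ncol(x$mean)),
         position = rep(x$positions, each = nrow(x$mean)),
         density = as.vector(x$mean), count = as.vector(x$count),
         sample_id = x$sample_id %||% NA_character_)
}

# count-weighted average of several codon_density_matrix objects
average_matrices <- function(mats) {
  if (inherits(mats, "codon_density_matrix")) return(mats)
  stopifnot(length(mats) >= 1)
  sums <- mats[[1]]$mean * mats[[1]]$count
  cnts <- mats[[1]]$count
  if (length(mats) > 1) for (m in mats[-1]) {
    s <- m$mean * m$count
    sums <- ifelse(is.na(sums), 0, sums) + ifelse(is.na(s), 0, s)
    cnts <- cnts + m$count
  }
  out <- mats[[1]]
  out$mean <- sums / ifelse(cnts > 0, cnts, NA_real_)
  out$count <- cnts
  out$sample_id <- NULL
  out
}
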