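# Brute-force oracle for relative density and the codon x position matrix:
# plain loops over positions, kept deliberately independent of the
# vectorized implementation.
oracle_rel_density <- function(track, models, h, eh, et) {
  out <- list()
  for (i in seq_len(nrow(models))) {
    L <- models$end[i] - models$start[i]
    d <- numeric(L)
    for (t in 0:(L - 1)) {
      g <- if (models$strand[i] == "+") models$start[i] + t else
        models$end[i] - 1 - t
      d[t + 1] <- track$depth[[models$strand[i]]][g + 1]
    }
    rel <- rep(NA_real_, L)
    for (t in 0:(L - 1)) {
      lo <- max(0, t - h); hi <- min(L - 1, t + h)
      if ((hi - lo + 1) / (2 * h + 1) < 0.5) next
      wm <- mean(d[(lo:hi) + 1])
      if (wm > 0) rel[t + 1] <- d[t + 1] / wm
    }
    out[[models$gene_id[i]]] <- list(d = d, rel = rel)
  }
  # frame factors over included codons
  ff <- numeric(3)
  for (k in 0:2) {
    acc <- c()
    for (i in seq_len(nrow(models))) {
      L <- models$end[i] - models$start[i]
      ns <- L / 3 - 1
      for (cc in eh:(ns - 1 - et)) {
        t <- 3 * cc + k
        acc <- c(acc, out[[models$gene_id[i]]]$rel[t + 1])
      }
    }
    m <- mean(acc, na.rm = TRUE)
    ff[k + 1] <- if (is.finite(m) && m != 0) m else NA_real_
  }
  for (g in names(out)) {
    L <- length(out[[g]]$rel)
    out[[g]]$rel_norm <- out[[g]]$rel / ff[(0:(L - 1)) %% 3 + 1]
  }
  list(genes = out, ff = ff)
}

oracle_matrix <- function(orc, models, genome, offset, positions, eh, et) {
  sc <- sense_codons()
  sums <- matrix(0, 61, length(positions),
                 dimnames = list(sc$codon, as.character(positions)))
  cnts <- sums
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    cds <- riboflux:::gene_sequence(genome, models$reference[i],
                                    models$start[i], models$end[i],
                                    models$strand[i])
    L <- models$end[i] - models$start[i]
    ns <- L / 3 - 1
    for (cc in eh:(ns - 1 - et)) {
      cdn <- substr(cds, 3 * cc + 1, 3 * cc + 3)
      if (!(cdn %in% sc$codon)) next
      for (j in seq_along(positions)) {
        t <- 3 * cc + offset - positions[j]
        if (t < 0 || t >= L) next
        v <- orc$genes[[g]]$rel_norm[t + 1]
        if (is.na(v)) next
        sums[cdn, j] <- sums[cdn, j] + v
        cnts[cdn, j] <- cnts[cdn, j] + 1
      }
    }
  }
  mm <- sums / ifelse(cnts > 0, cnts, NA)
  for (j in seq_along(positions)) {
    ok <- !is.na(mm[, j])
    wm <- sum(cnts[ok, j] * mm[ok, j]) / sum(cnts[ok, j])
    if (is.finite(wm) && wm > 0) mm[, j] <- mm[, j] / wm
  }
  list(mean = mm, count = cnts)
}

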