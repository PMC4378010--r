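# Readers/writers for the external formats the pipeline touches, and the
# per-strand depth-track container every density computation is built on.

#' Read gene models from BED6 or GFF3
#'
#' Parses a gene annotation into the internal 0-based, half-open, strand
#' explicit convention (BED is already 0-based half-open; GFF3 1-based
#' inclusive coordinates are converted). Gene identifiers must be unique.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A tibble with columns `gene_id`, `reference`, `start`, `end`,
#'   `strand` and `codon_eligible` (FALSE for CDS whose length is not a
#'   positive multiple of 3; such genes are kept for gene-level analyses but
#'   excluded from codon-level ones, with a warning).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- if (format == "bed") {
    as.character(gr$name)
  } else {
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    as.character(id)
  }
  if (anyNA(ids) || any(ids == "")) abort("gene annotation record without an id")
  models <- tibble(
    gene_id   = ids,
    reference = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end       = GenomicRanges::end(gr),
    strand    = as.character(GenomicRanges::strand(gr))
  )
  validate_gene_models(models)
  flag_codon_eligibility(models)
}

#' Write gene models to BED6 or GFF3
#'
#' Inverse of [read_gene_models()]; round-trips the core fields exactly.
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  validate_gene_models(models)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     models$reference, models$start, models$end,
                     models$gene_id, models$strand)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\triboflux\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       models$reference, models$start + 1L, models$end,
                       models$strand, models$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned reads as (reference, strand, 5'-end, 3'-end) records
#'
#' Reduces each mapped, primary alignment to the fields the depth analyses
#' need. On the minus strand the 5' end is the rightmost aligned base and
#' the 3' end the leftmost. SAM input is converted via BAM and parsed with
#' `GenomicAlignments` so soft-clipped bases never enter the end
#' coordinates; unmapped and secondary records are skipped and counted in
#' the returned `skipped` attribute. TSV input has a header and columns
#' `reference`, `strand`, `five_prime`, `three_prime` (0-based).
#'
#' @param path Path to a `.sam` or `.tsv` file.
#' @param format `"auto"`, `"sam"` or `"tsv"`.
#' @return A tibble with columns `reference`, `strand`, `five_prime`,
#'   `three_prime`, `read_length`, with attribute `skipped` (SAM only).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flags))
    n_total <- Rsamtools::countBam(bam)$records
    left  <- GenomicAlignments::start(ga) - 1L  # soft clips already excluded
    right <- GenomicAlignments::end(ga) - 1L
    str <- as.character(GenomicAlignments::strand(ga))
    out <- tibble(
      reference   = as.character(GenomicAlignments::seqnames(ga)),
      strand      = str,
      five_prime  = ifelse(str == "+", left, right),
      three_prime = ifelse(str == "+", right, left),
      read_length = right - left + 1L
    )
    attr(out, "skipped") <- n_total - nrow(out)
    return(out)
  }
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           reference = readr::col_character(),
                           strand = readr::col_character(),
                           five_prime = readr::col_integer(),
                           three_prime = readr::col_integer()))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed alignment table %s: line %d", path, probs$row[1] + 1L))
  }
  stopifnot_scalar_strand(out$strand)
  bad <- (out$strand == "+" & out$five_prime > out$three_prime) |
         (out$strand == "-" & out$five_prime < out$three_prime)
  if (any(bad)) {
    abort(sprintf("malformed alignment table %s: line %d violates strand/end order",
                  path, which(bad)[1] + 1L))
  }
  mutate(out, read_length = abs(.data$three_prime - .data$five_prime) + 1L)
}

#' Write alignment records to the 4-column TSV dialect
#' @param records Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path) {
  readr::write_tsv(records[, c("reference", "strand", "five_prime", "three_prime")],
                   path)
  invisible(path)
}

#' Build per-strand read-depth arrays over a reference
#'
#' `three_prime_only` mode adds 1 at each record's 3'-end position (the
#' analytic signal for A-site-resolved densities, since the nuclease cut
#' site is a fixed offset downstream of the decoding site);
#' `full_cover` adds 1 to every covered position.
#'
#' @param records Alignment tibble (one reference only).
#' @param mode `"three_prime_only"` or `"full_cover"`.
#' @param reference_length Length of the reference in nt; defaults to one
#'   past the rightmost aligned base.
#' @return A `depth_track` object: list with `reference`, `mode`, `length`
#'   and `depth` (named list of numeric vectors for `+` and `-`).
#' @export
build_depth_track <- function(records,
                              mode = c("three_prime_only", "full_cover"),
                              reference_length = NULL) {
  mode <- match.arg(mode)
  refs <- unique(records$reference)
  if (length(refs) > 1) {
    abort(paste0("records span multiple references: ", paste(refs, collapse = ", ")))
  }
  reference <- if (length(refs)) refs else NA_character_
  if (is.null(reference_length)) {
    reference_length <- if (nrow(records) == 0) 0L else
      max(records$five_prime, records$three_prime) + 1L
  }
  depth <- list()
  for (s in c("+", "-")) {
    r <- records[records$strand == s, , drop = FALSE]
    if (mode == "three_prime_only") {
      depth[[s]] <- as.numeric(tabulate(r$three_prime + 1L, nbins = reference_length))
    } else {
      if (nrow(r) == 0) {
        depth[[s]] <- numeric(reference_length)
      } else {
        lo <- pmin(r$five_prime, r$three_prime)
        hi <- pmax(r$five_prime, r$three_prime)
        cov <- IRanges::coverage(IRanges::IRanges(lo + 1L, hi + 1L),
                                 width = reference_length)
        depth[[s]] <- as.numeric(cov)
      }
    }
  }
  structure(list(reference = reference, mode = mode,
                 length = as.integer(reference_length), depth = depth),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s, %s, %d nt; mass + %.0f / - %.0f\n",
              x$reference, x$mode, x$length,
              sum(x$depth[["+"]]), sum(x$depth[["-"]])))
  invisible(x)
}

#' Tidy a depth track into a long tibble
#' @param x A `depth_track`.
#' @param ... Unused.
#' @return Tibble with `reference`, `strand`, `pos` (0-based), `depth`
#'   (zero positions dropped).
#' @export
as_tibble.depth_track <- function(x, ...) {
  bind_rows(lapply(c("+", "-"), function(s) {
    nz <- which(x$depth[[s]] != 0)
    tibble(reference = x$reference, strand = s, pos = nz - 1L,
           depth = x$depth[[s]][nz])
  }))
}

#' Write one strand of a depth track as bedGraph
#'
#' Depth is divided by `normalizer` (typically the sample's mean depth over
#' the total coding region, so that normalized tracks are comparable
#' between samples). Runs of equal depth are merged; zero runs are omitted.
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @param normalizer Positive scaling divisor.
#' @param strand Which strand to export.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path, normalizer = 1, strand = "+") {
  if (!is.numeric(normalizer) || normalizer <= 0) {
    abort("normalizer must be > 0")
  }
  d <- track$depth[[strand]] / normalizer
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths     # 0-based starts
  keep <- r$values != 0
  if (!any(keep)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(track$reference,
                               IRanges::IRanges(starts[keep] + 1L, ends[keep]),
                               score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a position/value tibble
#' @param path bedGraph path.
#' @return Tibble with `reference`, `pos` (0-based) and `value`, one row per
#'   nonzero position.
#' @export
read_bedgraph <- function(path) {
  if (length(readLines(path, n = 1)) == 0) {
    return(tibble(reference = character(), pos = integer(), value = numeric()))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(reference = as.character(GenomicRanges::seqnames(gr)),
         pos = GenomicRanges::start(gr) - 1L,
         width = GenomicRanges::width(gr),
         value = gr$score) |>
    dplyr::reframe(reference = rep(.data$reference, .data$width),
                   pos = .data$pos + sequence(.data$width) - 1L,
                   value = rep(.data$value, .data$width))
}
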