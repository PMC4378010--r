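# Internal coordinate helpers.
#
# Convention: genome intervals are 0-based, half-open, strand explicit.
# Transcript coordinates run 5'->3' along the coding strand, 0 = first base
# of the start codon. All conversions between the two happen here.

# genome positions (0-based) of transcript offsets tpos for one gene model
transcript_to_genome <- function(start, end, strand, tpos) {
  if (strand == "+") start + tpos else (end - 1L) - tpos
}

# extract the transcript-oriented depth vector of one gene from a depth track,
# optionally extended upstream/downstream (positions outside the reference -> NA)
transcript_depth <- function(track, start, end, strand,
                             from = 0L, to = (end - start) - 1L) {
  tpos <- seq.int(from, to)
  gpos <- transcript_to_genome(start, end, strand, tpos)
  d <- rep(NA_real_, length(gpos))
  ok <- gpos >= 0L & gpos < track$length
  d[ok] <- track$depth[[strand]][gpos[ok] + 1L]
  d
}

# transcript-oriented nucleotide sequence of a gene as a character scalar
gene_sequence <- function(genome, reference, start, end, strand) {
  seq <- Biostrings::subseq(genome[[reference]], start + 1L, end)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

# split a CDS sequence into codons (character vector); no frame checking here
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' The 61 sense codons and their amino acids
#'
#' Standard-code sense codons (DNA alphabet, alphabetical order) with
#' one-letter and three-letter amino-acid assignments. Used throughout the
#' codon-level analyses as the canonical codon axis.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter) and `aa3`.
#' @export
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all64 <- sort(all64)
  aa <- vapply(all64, function(cdn) {
    as.character(Biostrings::translate(Biostrings::DNAString(cdn),
                                       no.init.codon = TRUE))
  }, character(1))
  keep <- aa != "*"
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  tibble(codon = all64[keep], aa = unname(aa[keep]),
         aa3 = unname(three[aa[keep]]))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# named codon->aa lookup (61 sense codons)
codon_aa_map <- function() {
  sc <- sense_codons()
  setNames(sc$aa, sc$codon)
}

stopifnot_scalar_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(strand)
}

# validate a gene-models tibble; returns it invisibly
validate_gene_models <- function(models) {
  req <- c("gene_id", "reference", "start", "end", "strand")
  miss <- setdiff(req, names(models))
  if (length(miss)) {
    abort(paste0("gene models lack column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- models$gene_id[duplicated(models$gene_id)]
  if (length(dup)) {
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(models$end <= models$start)) abort("gene with end <= start")
  stopifnot_scalar_strand(models$strand)
  invisible(models)
}

# flag genes unusable for codon-level work (CDS not a codon multiple or < 3 nt)
flag_codon_eligibility <- function(models) {
  len <- models$end - models$start
  bad <- len < 3L | (len %% 3L) != 0L
  if (any(bad)) {
    warn(paste0("CDS length not a positive codon multiple; excluded from ",
                "codon-level analysis: ",
                paste(models$gene_id[bad], collapse = ", ")))
  }
  mutate(models, codon_eligible = !bad)
}
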