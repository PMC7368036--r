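#' Reference genome container
#'
#' A `ref_genome` holds named contig sequences (uppercase, alphabet
#' `{A,C,G,T,N}`) together with the genome-wide base composition over
#' `{A,C,G,T}` (`N` bases are excluded from the frequencies). It is the
#' coordinate authority for every event in the package: all coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param contigs Named character vector of nucleotide sequences. Lowercase is
#'   accepted; IUPAC ambiguity codes are collapsed to `N`.
#' @return An object of class `ref_genome` with elements `contigs` (named
#'   uppercase character vector) and `base_freqs` (named numeric over
#'   `A`, `C`, `G`, `T`, summing to 1 when any non-`N` base exists).
#' @examples
#' g <- ref_genome(c(c1 = "acgtACGT"))
#' g$base_freqs
#' @export
ref_genome <- function(contigs) {
  if (length(contigs) == 0) {
    abort("genome has no contigs")
  }
  nms <- names(contigs)
  if (is.null(nms) || any(!nzchar(nms))) {
    abort("all contigs must be named")
  }
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate contig name: ", nms[duplicated(nms)][1]))
  }
  seqs <- toupper(contigs)
  bad <- stringr::str_extract(seqs, "[^ACGTRYSWKMBDHVN]")
  if (any(!is.na(bad))) {
    abort(paste0("non-IUPAC character in sequence: '", bad[!is.na(bad)][1], "'"))
  }
  # ambiguity codes carry no usable base identity for junction scoring
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  structure(
    list(contigs = seqs, base_freqs = base_composition(seqs)),
    class = "ref_genome"
  )
}

base_composition <- function(seqs) {
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(unname(seqs)),
    letters = c("A", "C", "G", "T")
  )
  totals <- colSums(counts)
  n <- sum(totals)
  if (n == 0) {
    return(setNames(rep(NA_real_, 4), c("A", "C", "G", "T")))
  }
  totals / n
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$contigs), " contig(s), ",
      format(sum(nchar(x$contigs)), big.mark = ","), " bp\n", sep = "")
  cat("  base_freqs:",
      paste(names(x$base_freqs), round(x$base_freqs, 4), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Contig lengths of a reference genome
#'
#' @param genome A [ref_genome()].
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  nchar(genome$contigs)
}

#' Read a reference genome from FASTA
#'
#' Sequences may be wrapped over multiple lines and may be lowercase; they are
#' stored uppercase. Contig order is preserved. Duplicate contig names, empty
#' files and non-IUPAC characters are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A [ref_genome()].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(paste0("empty FASTA file: ", path))
  contigs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(ss))
  ref_genome(contigs)
}

#' Write a reference genome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome A [ref_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Fetch a genome slice
#'
#' Returns the half-open slice `[start, end)` of a contig, 0-based.
#' `fetch_seq(g, c, x, x)` is the empty string.
#'
#' @param genome A [ref_genome()].
#' @param contig Contig name.
#' @param start,end 0-based half-open coordinates, `0 <= start <= end <= `
#'   contig length.
#' @return A nucleotide string.
#' @examples
#' g <- ref_genome(c(c1 = "ACGT"))
#' fetch_seq(g, "c1", 1, 3) # "CG"
#' @export
fetch_seq <- function(genome, contig, start, end) {
  seq <- genome_contig(genome, contig)
  if (start < 0 || end < start || end > nchar(seq)) {
    abort(sprintf("coordinates [%d, %d) out of range for contig '%s' (length %d)",
                  start, end, contig, nchar(seq)))
  }
  substr(seq, start + 1L, end)
}

genome_contig <- function(genome, contig) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!contig %in% names(genome$contigs)) {
    abort(paste0("unknown contig: ", contig))
  }
  genome$contigs[[contig]]
}

# single base at 0-based position (no bounds check; callers validate)
base_at <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 1L)

#' Reverse complement of a nucleotide string
#'
#' @param x A nucleotide string over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
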