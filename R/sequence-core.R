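#' Validate and normalise a DNA sequence
#'
#' All sequences in the package are plain upper-case character strings over
#' `A`, `C`, `G`, `T`. Design inputs must be unambiguous, so `N` is rejected
#' unless `allow_n = TRUE` (sequencing reads legitimately contain `N`).
#' Coordinates everywhere in the package are 1-based and inclusive, matching
#' how positions are quoted in the splicing literature ("position 15" is the
#' fifteenth base of the intron).
#'
#' @param x Character vector of sequences (any case; `U` is accepted and
#'   converted to `T`).
#' @param allow_n Tolerate `N` bases?
#' @return Upper-case DNA character vector, same length as `x`.
#' @examples
#' dna("acgttu")
#' @export
dna <- function(x, allow_n = FALSE) {
  if (!is.character(x)) abort("sequences must be character strings")
  x <- chartr("U", "T", toupper(x))
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    offending <- gsub(sprintf("[%s]", alphabet), "", x[bad][1])
    abort(sprintf(
      "invalid character(s) '%s' in sequence%s",
      substr(offending, 1, 5),
      if (allow_n) "" else " (N not allowed in design inputs)"
    ))
  }
  x
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; an involution (`revcomp(revcomp(x)) == x`)
#' and identity on the empty string. `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AC") # "GT"
#' @export
revcomp <- function(x) {
  x <- dna(x, allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Display a DNA sequence with RNA lettering
#'
#' Sequences are stored as DNA throughout; hairpins are RNA in vivo, so
#' reports may render `T` as `U`. Formatting only -- no object ever holds `U`.
#'
#' @param x DNA character vector.
#' @return The same sequences with `T` replaced by `U`.
#' @export
as_rna_display <- function(x) chartr("T", "U", dna(x, allow_n = TRUE))

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons render as `*`. The frame offset is the
#' number of bases to skip before the first codon (0 for a clean ORF).
#'
#' @param cds DNA string.
#' @param frame_offset Bases skipped before the first codon (default 0).
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTAA") # "M*"
#' @export
translate_cds <- function(cds, frame_offset = 0) {
  cds <- dna(cds)
  body <- substr(cds, frame_offset + 1, nchar(cds))
  if (nchar(body) %% 3 != 0) {
    abort(sprintf("frame error: %d bases after offset %d is not a multiple of 3",
                  nchar(body), frame_offset))
  }
  if (nchar(body) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(body),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "error"))
}

#' Count purines (A/G) in a window
#'
#' Purines interrupting the polypyrimidine tract upstream of a 3' splice site
#' weaken acceptor recognition, so their count is a core design statistic.
#'
#' @param seq DNA string.
#' @param start,end 1-based inclusive window bounds (defaults: whole sequence).
#' @return Integer count of A/G in the window.
#' @examples
#' purine_count("GTTCTTCTTT") # 1
#' @export
purine_count <- function(seq, start = 1, end = nchar(seq)) {
  seq <- dna(seq, allow_n = TRUE)
  if (start < 1 || end > nchar(seq) || (end < start - 1)) {
    abort(sprintf("window [%d, %d] out of bounds for sequence of length %d",
                  start, end, nchar(seq)))
  }
  str_count(str_sub(seq, start, end), "[AG]")
}

#' @rdname purine_count
#' @export
pyrimidine_count <- function(seq, start = 1, end = nchar(seq)) {
  seq <- dna(seq, allow_n = TRUE)
  if (start < 1 || end > nchar(seq) || (end < start - 1)) {
    abort(sprintf("window [%d, %d] out of bounds for sequence of length %d",
                  start, end, nchar(seq)))
  }
  str_count(str_sub(seq, start, end), "[CT]")
}

#' Longest homopolymer run of a base
#'
#' Returns the maximal run of `base`, ties broken by leftmost start. A G-run
#' inside an intron can compensate for weak splice signals, and its position
#' matters (runs close to the donor may instead repress splicing).
#'
#' @param seq DNA string.
#' @param base Single base, one of A/C/G/T.
#' @return One-row tibble with `run_length` and `start` (1-based; `start` is
#'   `NA` and `run_length` 0 when the base is absent).
#' @export
longest_run <- function(seq, base) {
  seq <- dna(seq, allow_n = TRUE)
  base <- match.arg(toupper(base), c("A", "C", "G", "T"))
  r <- rle(strsplit(seq, "")[[1]])
  hit <- r$values == base
  if (!any(hit)) return(tibble(run_length = 0L, start = NA_integer_))
  best <- which(hit)[which.max(r$lengths[hit])]
  starts <- cumsum(c(1L, r$lengths))
  tibble(run_length = as.integer(r$lengths[best]),
         start = as.integer(starts[best]))
}
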