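#' Read and write FASTA / FASTQ as tibbles
#'
#' Thin tibble-returning wrappers around Biostrings' parsers. FASTA may be
#' wrapped or unwrapped, multi-record; FASTQ is 4-line, Phred+33. Round trips
#' (`write_*` then `read_*`) preserve names and bases exactly.
#'
#' @param path File path.
#' @param allow_n Tolerate `N` bases (default `TRUE` for reads, `FALSE` for
#'   design input via [read_fasta()]'s argument).
#' @return `read_fasta()`: tibble with `name`, `seq`. `read_fastq()`: tibble
#'   with `name`, `seq`, `qual`.
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  tibble(
    name = names(set) %||% as.character(seq_along(set)),
    seq  = unname(dna(as.character(set), allow_n = allow_n))
  )
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(name = names(set) %||% as.character(seq_along(set)),
         seq = unname(as.character(set)),
         qual = unname(as.character(S4Vectors::mcols(set)$qualities)))
  }, error = function(e) {
    abort(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  })
  if (any(nchar(parsed$qual) != nchar(parsed$seq))) {
    abort(sprintf("malformed FASTQ '%s': quality/sequence length mismatch (record %d)",
                  path, which(nchar(parsed$qual) != nchar(parsed$seq))[1]))
  }
  tibble(name = parsed$name, seq = dna(parsed$seq, allow_n = TRUE),
         qual = parsed$qual)
}

#' @rdname read_fasta
#' @param x Tibble with a `name` and `seq` column (plus `qual` for FASTQ).
#' @param width Line-wrap width for FASTA output.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("name", "seq") %in% names(x)))
  set <- Biostrings::DNAStringSet(dna(x$seq, allow_n = TRUE))
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("name", "seq", "qual") %in% names(x)))
  if (any(nchar(x$qual) != nchar(x$seq))) {
    abort("quality strings must match sequence lengths")
  }
  lines <- if (nrow(x) == 0) character(0) else
    as.vector(rbind(paste0("@", x$name), x$seq, rep("+", nrow(x)), x$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a hexamer motif set (one 6-mer per line)
#'
#' Plain-text motif lists, e.g. exonic splice enhancer (ESE) hexamers; `#`
#' starts a comment, blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of upper-case hexamers.
#' @export
read_hexamers <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  hx <- toupper(lines[nzchar(lines)])
  if (length(hx) == 0) abort(sprintf("no hexamers in '%s'", path))
  if (any(nchar(hx) != 6)) {
    abort(sprintf("malformed hexamer '%s' in '%s' (must be 6 nt)",
                  hx[nchar(hx) != 6][1], path))
  }
  dna(hx)
}

#' Read a codon usage table
#'
#' TSV with columns `codon`, `aa`, `fraction`, where `fraction` is the codon's
#' relative frequency within its synonymous family. Families are renormalised
#' to sum to exactly 1 so that downstream comparisons are scale-free.
#'
#' @param path File path; default is the packaged human table.
#' @return Tibble with `codon`, `aa`, `fraction`.
#' @export
read_codon_usage <- function(path = system.file("extdata", "codon_usage_human.tsv",
                                                package = "mirtronkr")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "aa", "fraction") %in% names(tab))) {
    abort("codon usage table needs columns codon, aa, fraction")
  }
  tab |>
    as_tibble() |>
    mutate(codon = dna(.data$codon)) |>
    group_by(.data$aa) |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    ungroup()
}

#' The packaged synthetic mirt-1cN-like hairpin fixture
#'
#' A reconstruction of a 5'-arm artificial mirtron with the sequence features
#' reported for mirt-1cN: donor hexamer GTGAGA (sub-optimal at two consensus
#' positions), four consecutive G residues starting at intron position 15,
#' a polypyrimidine tract GTTCTTCTTT with a single purine, and a terminal CAG.
#' The true published hairpin lives in figure/supplementary material; this
#' fixture is synthetic and intended for examples and tests, not therapy
#' design.
#'
#' @return One-row tibble with `name`, `seq`.
#' @export
mirt1cN_synthetic <- function() {
  read_fasta(system.file("extdata", "mirt1cN_synthetic.fasta",
                         package = "mirtronkr"))
}
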