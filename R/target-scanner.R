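#' Scan a transcript for splice-compatible mirtron target sites
#'
#' A mirtron guide strand is the reverse complement of a target window on the
#' sense mRNA, and must double as an intron terminus: a 5'-arm guide begins
#' the intron and so must start GT (the window therefore ends AC), while a
#' 3'-arm guide ends the intron and must end AG (the window starts CT). Both
#' arms are enumerated; the transcript is scanned sense-strand only since
#' RNAi acts on the mRNA.
#'
#' @param transcripts Tibble with `name` and `seq` columns (e.g. from
#'   [read_fasta()]) or a character vector of sequences (names optional).
#' @param guide_length Mature guide length; default 21, sensible range 19-23.
#' @param arm Which hairpin arm(s) to consider for the guide.
#' @return Tibble of candidate sites ordered by (transcript, start, arm):
#'   `transcript`, `start`, `end` (1-based inclusive window on the sense
#'   strand), `arm`, `window`, `guide`.
#' @examples
#' scan_targets("CCGTAAGTACTTACCC", guide_length = 6)
#' @export
scan_targets <- function(transcripts, guide_length = 21,
                         arm = c("both", "5p", "3p")) {
  arm <- match.arg(arm)
  if (guide_length < 19 || guide_length > 23) {
    warn("guide lengths outside 19-23 are unusual for mirtron designs")
  }
  if (guide_length < 4) abort("guide_length too short")
  tx <- as_seq_tbl(transcripts)
  out <- purrr::pmap(tx, function(name, seq) {
    L <- nchar(seq)
    if (L < guide_length) {
      return(tibble(transcript = character(), start = integer(),
                    end = integer(), arm = character(),
                    window = character(), guide = character()))
    }
    starts <- seq_len(L - guide_length + 1L)
    windows <- str_sub(seq, starts, starts + guide_length - 1L)
    res <- list()
    if (arm %in% c("both", "5p")) {
      keep <- str_sub(windows, -2, -1) == "AC"
      res$p5 <- tibble(transcript = name, start = starts[keep],
                       end = starts[keep] + guide_length - 1L, arm = "5p",
                       window = windows[keep])
    }
    if (arm %in% c("both", "3p")) {
      keep <- str_sub(windows, 1, 2) == "CT"
      res$p3 <- tibble(transcript = name, start = starts[keep],
                       end = starts[keep] + guide_length - 1L, arm = "3p",
                       window = windows[keep])
    }
    bind_rows(res)
  })
  bind_rows(out) |>
    mutate(guide = revcomp(.data$window)) |>
    arrange(.data$transcript, .data$start, .data$arm)
}

#' Score candidate target sites
#'
#' Adds the three design criteria and their weighted composite to a site
#' table from [scan_targets()]:
#' * `donor_consensus_score` - for 5'-arm guides, match of the guide's first
#'   six bases (the future donor) to GTAAGT; 3'-arm guides get a neutral 1
#'   because their donor lies on the freely designable passenger arm.
#' * `ppt_score` - for 3'-arm guides, purity of the 10-nt polypyrimidine
#'   tract immediately 5' of the guide's terminal NAG (each purine
#'   interruption costs 0.1); 5'-arm guides get a neutral 1 since their
#'   tract is carried by the editable passenger.
#' * `end_bias_score` - achievable RISC-loading asymmetry: G/C enrichment of
#'   the guide's 3'-terminal four bases over its 5'-terminal four, mapped to
#'   \[0, 1\].
#'
#' @param sites Tibble from [scan_targets()].
#' @param weights Named weights for `donor`, `ppt`, `end_bias`
#'   (defaults 0.4 / 0.4 / 0.2).
#' @return Input tibble with `donor_mismatches`, `donor_consensus_score`,
#'   `ppt_interruptions`, `ppt_score`, `end_bias_score`, `composite` added.
#' @export
score_targets <- function(sites,
                          weights = c(donor = 0.4, ppt = 0.4, end_bias = 0.2)) {
  if (nrow(sites) == 0) {
    return(mutate(sites, donor_mismatches = integer(),
                  donor_consensus_score = double(),
                  ppt_interruptions = integer(), ppt_score = double(),
                  end_bias_score = double(), composite = double()))
  }
  gl <- nchar(sites$guide)
  don <- score_donor(str_sub(sites$guide, 1, 6))
  is5 <- sites$arm == "5p"
  tract <- str_sub(sites$guide, gl - 12, gl - 3) # 10 nt before terminal NAG
  interruptions <- str_count(tract, "[AG]")
  gc4 <- function(x) str_count(x, "[GC]") / 4
  end_bias <- (gc4(str_sub(sites$guide, -4, -1)) -
                 gc4(str_sub(sites$guide, 1, 4)) + 1) / 2
  sites |>
    mutate(
      donor_mismatches = ifelse(is5, don$mismatch_count, NA_integer_),
      donor_consensus_score = ifelse(is5, don$consensus_score, 1),
      ppt_interruptions = ifelse(is5, NA_integer_, as.integer(interruptions)),
      ppt_score = ifelse(is5, 1, 1 - interruptions / 10),
      end_bias_score = end_bias,
      composite = weights[["donor"]] * .data$donor_consensus_score +
        weights[["ppt"]] * .data$ppt_score +
        weights[["end_bias"]] * .data$end_bias_score
    )
}

#' Off-target specificity counts for guides by exhaustive k-mer search
#'
#' Counts occurrences of each guide's target (the reverse complement of the
#' guide) across a transcriptome: exact, within `max_mismatch` substitutions,
#' and occurrences of the seed-complement (reverse complement of guide
#' positions 2-8, the region dominating target recognition). A BLAST-style
#' heuristic is deliberately not used; transcripts are scanned exhaustively.
#'
#' @param sites Site tibble with a `guide` column (or character vector of
#'   guides, which is wrapped into one).
#' @param transcriptome Tibble with `name`/`seq` or character vector.
#' @param max_mismatch Mismatch allowance for `k_mismatch_hits` (default 2).
#' @param seed Guide positions treated as seed (default 2:8).
#' @return Sites tibble with `exact_hits`, `k_mismatch_hits`,
#'   `seed_complement_hits`, `searched_transcripts` added.
#' @export
specificity_counts <- function(sites, transcriptome, max_mismatch = 2,
                               seed = 2:8) {
  if (is.character(sites)) sites <- tibble(guide = dna(sites))
  tx <- if (length(transcriptome) == 0 ||
            (is.data.frame(transcriptome) && nrow(transcriptome) == 0)) {
    tibble(name = character(), seq = character())
  } else {
    as_seq_tbl(transcriptome)
  }
  subjects <- Biostrings::DNAStringSet(tx$seq)
  count_hits <- function(pattern, mm) {
    if (length(subjects) == 0) return(0L)
    sum(Biostrings::vcountPattern(pattern, subjects, max.mismatch = mm))
  }
  sites |>
    mutate(
      exact_hits = map_int(.data$guide, ~ count_hits(revcomp(.x), 0)),
      k_mismatch_hits = map_int(.data$guide, ~ count_hits(revcomp(.x), max_mismatch)),
      seed_complement_hits = map_int(
        .data$guide,
        ~ count_hits(revcomp(str_sub(.x, min(seed), max(seed))), 0)
      ),
      searched_transcripts = length(subjects)
    )
}

#' Rank scored target sites
#'
#' Descending composite score with a stable tie-break on (transcript, start,
#' arm), so equal-scoring sites keep their positional order.
#'
#' @param sites Tibble from [score_targets()].
#' @return The same tibble, reordered, with a `rank` column.
#' @export
rank_targets <- function(sites) {
  if (!"composite" %in% names(sites)) {
    abort("sites must be scored (score_targets) before ranking")
  }
  if (any(is.na(sites$composite))) abort("composite scores contain NA")
  sites |>
    arrange(desc(.data$composite), .data$transcript, .data$start, .data$arm) |>
    mutate(rank = row_number())
}

# coerce character / tibble input into a (name, seq) tibble
as_seq_tbl <- function(x, allow_n = FALSE) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "seq") %in% names(x)))
    tibble(name = as.character(x$name), seq = dna(x$seq, allow_n = allow_n))
  } else {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    tibble(name = nm, seq = dna(unname(x), allow_n = allow_n))
  }
}
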