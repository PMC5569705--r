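DONOR_CONSENSUS <- "GTAAGT"

#' Score a 5' splice-donor hexamer against the GTAAGT consensus
#'
#' Per-position comparison of the first six intron bases to the strong
#' mammalian donor consensus. A weak donor (e.g. two mismatches) can still
#' splice, but efficiency suffers; for 5'-arm mirtrons the donor is part of
#' the miRNA seed and cannot be freely improved.
#'
#' @param hexamer Character vector of 6-mers (intron positions +1..+6).
#' @param pwm Optional 4 x 6 position weight matrix (rows named A, C, G, T);
#'   when supplied, a `pwm_score` column (sum of per-position weights) is
#'   added to the consensus comparison.
#' @return Tibble with `hexamer`, `mismatch_count`, `mismatch_positions`
#'   (list of ascending 1-based positions), `consensus_score` in \[0, 1\],
#'   and `pwm_score` when a matrix was given.
#' @examples
#' score_donor("GTGAGA") # two mismatches
#' @export
score_donor <- function(hexamer, pwm = NULL) {
  hexamer <- dna(hexamer)
  if (any(nchar(hexamer) != 6)) abort("donor hexamers must be exactly 6 nt")
  cons <- strsplit(DONOR_CONSENSUS, "")[[1]]
  res <- map(hexamer, function(h) {
    b <- strsplit(h, "")[[1]]
    which(b != cons)
  })
  out <- tibble(
    hexamer = hexamer,
    mismatch_count = map_int(res, length),
    mismatch_positions = map(res, as.integer),
    consensus_score = (6 - map_int(res, length)) / 6
  )
  if (!is.null(pwm)) {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4, ncol(pwm) == 6,
              all(c("A", "C", "G", "T") %in% rownames(pwm)))
    out$pwm_score <- map_dbl(hexamer, function(h) {
      b <- strsplit(h, "")[[1]]
      sum(pwm[cbind(match(b, rownames(pwm)), 1:6)])
    })
  }
  out
}

#' Score a 3' splice-acceptor region
#'
#' Takes the last 13 intron bases: a 10-nt polypyrimidine tract (PPT) followed
#' by the terminal trinucleotide. A valid acceptor must end in AG; CAG is the
#' strongest terminal context. Purines interrupting the PPT lower the score.
#'
#' @param tail Character vector; the last 13 (or more) intron bases. Only the
#'   final 13 are scored.
#' @return Tibble with `tail13`, `valid` (terminal AG present),
#'   `terminal3`, `ppt_interruptions` (purines in the 10-nt tract),
#'   `ppt_purity` and `acceptor_score` in \[0, 1\] (0 when invalid).
#' @examples
#' score_acceptor("GTTCTTCTTTCAG")
#' @export
score_acceptor <- function(tail) {
  tail <- dna(tail, allow_n = TRUE)
  if (any(nchar(tail) < 13)) abort("acceptor scoring needs at least 13 nt")
  t13 <- str_sub(tail, -13, -1)
  tract <- str_sub(t13, 1, 10)
  term <- str_sub(t13, 11, 13)
  valid <- str_sub(term, 2, 3) == "AG"
  term_score <- dplyr::case_when(
    term == "CAG" ~ 1.0,
    term == "TAG" ~ 0.8,
    valid ~ 0.5,
    TRUE ~ 0.0
  )
  interruptions <- str_count(tract, "[AG]")
  purity <- 1 - interruptions / 10
  tibble(
    tail13 = t13,
    valid = valid,
    terminal3 = term,
    ppt_interruptions = as.integer(interruptions),
    ppt_purity = purity,
    acceptor_score = ifelse(valid, 0.6 * purity + 0.4 * term_score, 0)
  )
}

#' Find G-triplets (runs of three or more G) in an intron
#'
#' Intronic G-runs can compensate for weak donor/PPT signals, but a run close
#' to the 5' splice site may instead repress splicing; hits within
#' `proximity_limit` of the donor are flagged.
#'
#' @param intron DNA string.
#' @param min_length Minimum run length (default 3).
#' @param proximity_limit Distance (nt, 1-based start) below which a run is
#'   flagged donor-proximal (default 15).
#' @return Tibble with `start`, `run_length`, `donor_proximal`.
#' @export
find_g_triplets <- function(intron, min_length = 3, proximity_limit = 15) {
  intron <- dna(intron, allow_n = TRUE)
  r <- rle(strsplit(intron, "")[[1]])
  starts <- cumsum(c(1L, r$lengths))
  hit <- r$values == "G" & r$lengths >= min_length
  tibble(
    start = as.integer(starts[which(hit)]),
    run_length = as.integer(r$lengths[hit]),
    donor_proximal = starts[which(hit)] <= proximity_limit
  )
}

#' Locate the best branch-point candidate in an intron
#'
#' Scans for the degenerate YTNAY motif (branch adenosine at position 4)
#' with the branch A between 15 and 45 nt upstream of the intron 3' end.
#' Purely diagnostic: absence is reported, never fatal.
#'
#' @param intron DNA string.
#' @param window Distance range (nt from 3' end) searched for the branch A.
#' @return Tibble (0 or 1 rows) with `start` (motif start, 1-based),
#'   `branch_a` (position of the A), `motif`, `score` (fraction of the five
#'   positions matching YTNAY). Two equal-scoring motifs tie-break towards
#'   the 3' splice site.
#' @export
find_branch_point <- function(intron, window = c(15, 45)) {
  intron <- dna(intron, allow_n = TRUE)
  L <- nchar(intron)
  empty <- tibble(start = integer(), branch_a = integer(),
                  motif = character(), score = double())
  if (L < 25) return(empty)
  match1 <- function(b, cls) {
    switch(cls, Y = b %in% c("C", "T"), N = TRUE, b == cls)
  }
  pattern <- c("Y", "T", "N", "A", "Y")
  cand <- tibble(branch_a = seq_len(L)) |>
    filter(L - .data$branch_a >= window[1], L - .data$branch_a <= window[2]) |>
    mutate(start = .data$branch_a - 3L) |>
    filter(.data$start >= 1, .data$start + 4L <= L)
  if (nrow(cand) == 0) return(empty)
  cand <- cand |>
    mutate(
      motif = str_sub(intron, .data$start, .data$start + 5L - 1L),
      score = map_dbl(.data$motif, function(m) {
        b <- strsplit(m, "")[[1]]
        mean(mapply(match1, b, pattern))
      })
    ) |>
    filter(substr(.data$motif, 4, 4) == "A") |>
    arrange(desc(.data$score), desc(.data$branch_a))
  if (nrow(cand) == 0) return(empty)
  cand[1, c("start", "branch_a", "motif", "score")]
}

#' Scan exonic context flanking a splice junction for ESE hexamers
#'
#' An exonic splice enhancer (ESE) hit is a set hexamer whose start lies
#' 5-10 bases from the junction on either exonic side. Offsets are signed:
#' negative = upstream exon (e.g. -7), positive = downstream (+10), with
#' -1/+1 the bases immediately flanking the junction. The hexamer itself may
#' extend across the junction since the exons are contiguous before intron
#' insertion.
#'
#' @param upstream,downstream Exonic context (typically 20 nt each side).
#' @param hexamers Character vector of ESE 6-mers (see [read_hexamers()]).
#' @param window Absolute start-offset range counted as a hit (default 5-10).
#' @return Tibble with `hexamer`, `offset` (signed start), `side` (up/down).
#' @export
scan_ese <- function(upstream, downstream, hexamers, window = c(5, 10)) {
  upstream <- dna(upstream, allow_n = TRUE)
  downstream <- dna(downstream, allow_n = TRUE)
  hexamers <- dna(hexamers)
  if (length(hexamers) == 0) abort("ESE hexamer set is empty")
  if (any(nchar(hexamers) != 6)) abort("ESE entries must be 6 nt")
  nu <- nchar(upstream)
  full <- paste0(upstream, downstream)
  offsets <- c(-(window[2]:window[1]), window[1]:window[2])
  idx <- ifelse(offsets < 0, nu + offsets + 1L, nu + offsets)
  ok <- idx >= 1 & (idx + 5L) <= nchar(full)
  offsets <- offsets[ok]; idx <- idx[ok]
  hex_at <- str_sub(full, idx, idx + 5L)
  hit <- hex_at %in% hexamers
  tibble(
    hexamer = hex_at[hit],
    offset = as.integer(offsets[hit]),
    side = ifelse(offsets[hit] < 0, "up", "down")
  ) |>
    arrange(.data$offset)
}

#' Rank candidate mirtron insertion junctions within a transgene
#'
#' Enumerates exon-exon junctions (positions where the upstream exon ends in
#' AG, the minimal requirement for re-ligation of a clean acceptor) and scores
#' each by: similarity of the flanking bases to the favoured exonic context
#' CAAG|G; ESE hexamer support within 5-10 nt of the junction; a first-exon
#' length penalty (splicing degrades as the first exon grows past the ~374 nt
#' human average and becomes poor past ~800 nt); and distance from the 3'
#' end, standing in for coupling between splicing and polyadenylation.
#'
#' @param cds Transgene coding sequence (DNA string).
#' @param hexamers ESE hexamer set; `NULL` disables the ESE component.
#' @param context Exonic context taken from each side (default 20 nt).
#' @param weights Named numeric weights for `consensus`, `ese`, `first_exon`,
#'   `dist3` (defaults 0.5 / 0.2 / 0.2 / 0.1).
#' @param first_exon_soft,first_exon_scale Soft threshold (374 nt) and decay
#'   scale (430 nt, reaching ~e^-1 by the 804 nt "large first exon" mark) of
#'   the first-exon penalty.
#' @return Tibble, descending `composite`: `cds_position` (junction after
#'   this base), `context_up`, `context_down`, `consensus_score`, `n_ese`,
#'   `ese` (nested hit tibbles), `first_exon_len`, `dist_to_polya`,
#'   `composite`.
#' @export
find_insertion_sites <- function(cds, hexamers = NULL, context = 20,
                                 weights = c(consensus = 0.5, ese = 0.2,
                                             first_exon = 0.2, dist3 = 0.1),
                                 first_exon_soft = 374,
                                 first_exon_scale = 430) {
  cds <- dna(cds)
  L <- nchar(cds)
  favored <- c("C", "A", "A", "G", "G") # last four exonic bases + first of next exon
  pos <- which(strsplit(cds, "")[[1]] == "G")
  pos <- pos[pos >= 2 & pos < L & str_sub(cds, pos - 1, pos - 1) == "A"]
  if (length(pos) == 0) {
    return(tibble(cds_position = integer(), context_up = character(),
                  context_down = character(), consensus_score = double(),
                  n_ese = integer(), ese = list(), first_exon_len = integer(),
                  dist_to_polya = integer(), composite = double()))
  }
  sites <- tibble(cds_position = as.integer(pos)) |>
    mutate(
      context_up = str_sub(cds, pmax(1, .data$cds_position - context + 1), .data$cds_position),
      context_down = str_sub(cds, .data$cds_position + 1,
                             pmin(L, .data$cds_position + context)),
      consensus_score = map_dbl(.data$cds_position, function(j) {
        bases <- c(
          if (j >= 4) strsplit(str_sub(cds, j - 3, j), "")[[1]] else rep(NA, 4),
          substr(cds, j + 1, j + 1)
        )
        mean(bases == favored, na.rm = TRUE)
      }),
      ese = map2(.data$context_up, .data$context_down, function(u, d) {
        if (is.null(hexamers)) {
          tibble(hexamer = character(), offset = integer(), side = character())
        } else {
          scan_ese(u, d, hexamers)
        }
      }),
      n_ese = map_int(.data$ese, nrow),
      first_exon_len = .data$cds_position,
      dist_to_polya = L - .data$cds_position,
      first_exon_score = exp(-pmax(0, .data$first_exon_len - first_exon_soft) /
                               first_exon_scale),
      dist3_score = exp(-.data$dist_to_polya / 2000),
      ese_score = pmin(.data$n_ese, 4) / 4,
      composite = weights[["consensus"]] * .data$consensus_score +
        weights[["ese"]] * .data$ese_score +
        weights[["first_exon"]] * .data$first_exon_score +
        weights[["dist3"]] * .data$dist3_score
    ) |>
    arrange(desc(.data$composite), .data$cds_position)
  sites[, c("cds_position", "context_up", "context_down", "consensus_score",
            "n_ese", "ese", "first_exon_len", "dist_to_polya",
            "first_exon_score", "dist3_score", "composite")]
}

#' Enumerate spliced products of a construct with annotated splice sites
#'
#' Every donor/acceptor pairing with the donor upstream of the acceptor is a
#' possible product: the designed pair is "intended", all others "cryptic"
#' (e.g. a cryptic donor 69 nt upstream removes an extra 69 bases), and the
#' unspliced full-length transcript is always included.
#'
#' @param construct_length Total construct length (nt), or a DNA string whose
#'   length is used.
#' @param donors Integer positions of the first intron base (the G of GT) of
#'   each annotated donor.
#' @param acceptors Integer positions of the last intron base (the G of AG).
#' @param intended Length-2 integer `c(donor, acceptor)` naming the designed
#'   pair; must be members of `donors`/`acceptors`.
#' @return Tibble with `donor`, `acceptor`, `excised`, `product_length`,
#'   `classification` (intended / cryptic / unspliced).
#' @export
predict_splice_products <- function(construct_length, donors, acceptors,
                                    intended = c(donors[1], acceptors[1])) {
  if (is.character(construct_length)) {
    construct_length <- nchar(dna(construct_length, allow_n = TRUE))
  }
  donors <- as.integer(donors); acceptors <- as.integer(acceptors)
  if (length(donors) < 1 || length(acceptors) < 1) {
    abort("need at least one donor and one acceptor")
  }
  if (any(c(donors, acceptors) < 1) || any(c(donors, acceptors) > construct_length)) {
    abort("splice annotations outside the construct")
  }
  if (!(intended[1] %in% donors && intended[2] %in% acceptors) ||
      intended[1] >= intended[2]) {
    abort("intended pair must be an annotated donor upstream of an annotated acceptor")
  }
  pairs <- tidyr::expand_grid(donor = donors, acceptor = acceptors) |>
    filter(.data$donor < .data$acceptor) |>
    mutate(
      excised = .data$acceptor - .data$donor + 1L,
      product_length = construct_length - .data$excised,
      classification = ifelse(.data$donor == intended[1] &
                                .data$acceptor == intended[2],
                              "intended", "cryptic")
    )
  bind_rows(
    pairs,
    tibble(donor = NA_integer_, acceptor = NA_integer_, excised = 0L,
           product_length = as.integer(construct_length),
           classification = "unspliced")
  ) |>
    arrange(.data$classification != "intended", .data$product_length)
}
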