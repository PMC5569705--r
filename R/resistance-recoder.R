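#' Silently recode a coding region for RNAi resistance
#'
#' Every codon overlapping the target interval is, as far as possible,
#' replaced with a synonymous alternative: the candidate maximising
#' nucleotide differences from the original codon, tie-broken by the closest
#' codon-usage fraction, so the recoded gene escapes guide pairing while
#' keeping a comparable usage profile. Met and Trp have no synonym and stop
#' codons are never altered; both produce warnings rather than changes.
#' The protein sequence is invariant by construction.
#'
#' @param cds Coding sequence (DNA string, frame starting at base 1 after
#'   `frame_offset`).
#' @param target_interval Length-2 integer `c(start, end)`, 1-based inclusive
#'   on `cds`: the mirtron target window to recode.
#' @param usage Codon usage tibble (see [read_codon_usage()]).
#' @param frame_offset Bases before the first codon (default 0).
#' @param min_fraction Candidates with family usage below this floor are
#'   rejected (default 0.05) unless nothing else exists.
#' @return A `recoding_result` list: `original`, `recoded` (full CDS),
#'   `original_region`, `recoded_region`, `changes` (per-codon tibble),
#'   `nt_changes`, `warnings`, `target_interval`. `tidy()` returns the
#'   per-codon change log; `glance()` a one-row summary.
#' @export
recode <- function(cds, target_interval, usage = read_codon_usage(),
                   frame_offset = 0, min_fraction = 0.05) {
  cds <- dna(cds)
  if (nrow(usage) == 0) abort("empty codon usage table")
  L <- nchar(cds)
  ti <- as.integer(target_interval)
  if (length(ti) != 2 || ti[1] < 1 || ti[2] > L || ti[1] > ti[2]) {
    abort("target_interval out of bounds")
  }
  body_len <- L - frame_offset
  if (body_len %% 3 != 0) abort("frame error: CDS length minus offset not a multiple of 3")
  if (ti[1] <= frame_offset) abort("target_interval starts before the reading frame")
  codon_starts <- seq(frame_offset + 1, L - 2, by = 3)
  overlap <- codon_starts[codon_starts + 2 >= ti[1] & codon_starts <= ti[2]]
  code <- Biostrings::GENETIC_CODE
  usage_of <- setNames(usage$fraction, usage$codon)
  out <- cds
  warnings <- character()
  changes <- list()
  for (s in overlap) {
    old <- str_sub(cds, s, s + 2)
    aa <- unname(code[old])
    if (aa == "*") { # stop codons never altered
      warnings <- c(warnings, sprintf("stop codon %s at %d left unaltered", old, s))
      next
    }
    syn <- setdiff(names(code)[code == aa], old)
    if (length(syn) == 0) {
      warnings <- c(warnings,
                    sprintf("no synonymous alternative for %s (%s) at %d", old, aa, s))
      next
    }
    above_floor <- syn[!is.na(usage_of[syn]) & usage_of[syn] >= min_fraction]
    if (length(above_floor) > 0) syn <- above_floor
    diffs <- map_int(syn, ~ codon_hamming(old, .x))
    usage_gap <- abs(usage_of[syn] - usage_of[old])
    usage_gap[is.na(usage_gap)] <- Inf
    pick <- syn[order(-diffs, usage_gap, syn)][1]
    str_sub(out, s, s + 2) <- pick
    changes <- c(changes, list(tibble(
      codon_start = as.integer(s), aa = aa, old = old, new = pick,
      nt_diff = codon_hamming(old, pick),
      usage_old = unname(usage_of[old]), usage_new = unname(usage_of[pick])
    )))
  }
  changes <- if (length(changes)) bind_rows(changes) else
    tibble(codon_start = integer(), aa = character(), old = character(),
           new = character(), nt_diff = integer(),
           usage_old = double(), usage_new = double())
  if (translate_cds(out, frame_offset) != translate_cds(cds, frame_offset)) {
    abort("internal error: recoding altered the protein") # defensive; cannot happen
  }
  structure(list(
    original = cds, recoded = out,
    original_region = str_sub(cds, ti[1], ti[2]),
    recoded_region = str_sub(out, ti[1], ti[2]),
    target_interval = ti,
    changes = changes,
    nt_changes = string_hamming(cds, out),
    warnings = warnings
  ), class = "recoding_result")
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

string_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' @export
print.recoding_result <- function(x, ...) {
  cat(sprintf("<recoding_result> %d nt changed over %d codons in [%d, %d]\n",
              x$nt_changes, nrow(x$changes), x$target_interval[1],
              x$target_interval[2]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recoding_result <- function(x, ...) x$changes

#' @exportS3Method generics::glance
glance.recoding_result <- function(x, ...) {
  tibble(
    nt_changes = x$nt_changes,
    codons_changed = nrow(x$changes),
    region_length = nchar(x$original_region),
    n_warnings = length(x$warnings)
  )
}

#' Verify RNAi resistance of a recoded region against a guide
#'
#' Aligns the guide's target (its reverse complement) to the recoded region
#' at the offset with the fewest mismatches and reports total and
#' seed-region mismatch counts against configurable thresholds. A single
#' mismatch can dent silencing, but several (especially in the seed) are
#' needed for dependable resistance; the defaults require at least 4 total
#' and 2 in the seed.
#'
#' @param region Recoded target region (>= guide length).
#' @param guide Guide sequence.
#' @param min_total,min_seed Thresholds for a pass (defaults 4 and 2).
#' @param seed Guide positions forming the seed (default 2:8).
#' @return One-row tibble: `offset`, `total_mismatches`, `seed_mismatches`,
#'   `pass`.
#' @export
verify_resistance <- function(region, guide, min_total = 4, min_seed = 2,
                              seed = 2:8) {
  region <- dna(region); guide <- dna(guide)
  Lg <- nchar(guide); Lr <- nchar(region)
  if (Lr < Lg) abort("region shorter than guide")
  target <- revcomp(guide)
  tb <- strsplit(target, "")[[1]]
  best <- NULL
  for (off in 0:(Lr - Lg)) {
    wb <- strsplit(str_sub(region, off + 1, off + Lg), "")[[1]]
    mm <- wb != tb
    if (is.null(best) || sum(mm) < best$total) {
      best <- list(off = off, mm = mm, total = sum(mm))
    }
  }
  # guide position j pairs window position Lg - j + 1
  seed_mm <- sum(best$mm[Lg - seed + 1])
  tibble(
    offset = best$off + 1L,
    total_mismatches = as.integer(best$total),
    seed_mismatches = as.integer(seed_mm),
    pass = best$total >= min_total && seed_mm >= min_seed
  )
}

#' Audit a recoded region for newly created splice signals
#'
#' Recoding near an insertion junction can accidentally create splice
#' signals. Flags, relative to the original sequence: new GT-starting
#' hexamers within 2 mismatches of the donor consensus; new AG dinucleotides
#' whose upstream 13-nt context forms a plausible acceptor (<= 3 tract
#' purines); and the net change in ESE hexamer occurrences.
#'
#' @param original,recoded Same-length DNA strings (region plus flanks).
#' @param hexamers ESE set for the gain/loss audit; `NULL` skips it.
#' @return List with `donor_warnings`, `acceptor_warnings` (tibbles of
#'   position/sequence) and `ese_delta` (recoded minus original occurrence
#'   count, `NA` when no set given).
#' @export
audit_new_signals <- function(original, recoded, hexamers = NULL) {
  original <- dna(original); recoded <- dna(recoded)
  if (nchar(original) != nchar(recoded)) abort("sequences must align (equal length)")
  donor_like <- function(x) {
    L <- nchar(x)
    if (L < 6) return(tibble(position = integer(), hexamer = character(),
                             mismatch_count = integer()))
    starts <- seq_len(L - 5)
    hex <- str_sub(x, starts, starts + 5)
    keep <- str_sub(hex, 1, 2) == "GT"
    sc <- score_donor(hex[keep])
    tibble(position = starts[keep], hexamer = hex[keep],
           mismatch_count = sc$mismatch_count) |>
      filter(.data$mismatch_count <= 2)
  }
  acceptor_like <- function(x) {
    L <- nchar(x)
    pos <- which(strsplit(x, "")[[1]] == "G")
    pos <- pos[pos >= 13 & pos >= 2 &
                 str_sub(x, pos - 1, pos - 1) == "A"]
    if (length(pos) == 0) return(tibble(position = integer(), tail13 = character()))
    sc <- score_acceptor(str_sub(x, pos - 12, pos))
    tibble(position = pos, tail13 = sc$tail13)[sc$valid & sc$ppt_interruptions <= 3, ]
  }
  key <- function(df) paste(df$position, df[[2]])
  d_old <- donor_like(original); d_new <- donor_like(recoded)
  a_old <- acceptor_like(original); a_new <- acceptor_like(recoded)
  ese_delta <- NA_integer_
  if (!is.null(hexamers)) {
    count_all <- function(x) {
      starts <- seq_len(max(nchar(x) - 5, 0))
      sum(str_sub(x, starts, starts + 5) %in% hexamers)
    }
    ese_delta <- count_all(recoded) - count_all(original)
  }
  list(
    donor_warnings = d_new[!(key(d_new) %in% key(d_old)), ],
    acceptor_warnings = a_new[!(key(a_new) %in% key(a_old)), ],
    ese_delta = ese_delta
  )
}
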