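#' Default simulation parameters for mirtron small-RNA libraries
#'
#' The defaults emulate the published behaviour of a well-processed 5'-arm
#' mirtron library: a strong guide(5')-arm bias (arm fraction 0.986), high
#' 5'-end fidelity (0.988 of guide reads start at the intended +1 base),
#' modal read length 22 on the 5' arm and 20 on the 3' arm, and a small
#' per-base substitution error rate.
#'
#' @param n_reads Number of reads to draw.
#' @param arm5_prob Probability a read derives from the 5' arm.
#' @param start_jitter Named probability vector of 5'-start offsets
#'   (names are signed integer offsets; must sum to 1).
#' @param len5,len3 Named probability vectors of read lengths per arm.
#' @param error_rate Per-base substitution error probability.
#' @param seed Mandatory RNG seed for reproducibility.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_reads = 10000,
                       arm5_prob = 0.986,
                       start_jitter = c("0" = 0.988, "1" = 0.008, "-1" = 0.004),
                       len5 = c("20" = 0.15, "21" = 0.25, "22" = 0.46, "23" = 0.14),
                       len3 = c("19" = 0.20, "20" = 0.42, "21" = 0.25, "22" = 0.13),
                       error_rate = 0.001,
                       seed = 1L) {
  check_dist <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      abort(sprintf("%s must be a named probability vector", what))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("%s probabilities must be non-negative and sum to 1", what))
    }
  }
  check_dist(start_jitter, "start_jitter")
  check_dist(len5, "len5"); check_dist(len3, "len3")
  if (arm5_prob < 0 || arm5_prob > 1) abort("arm5_prob must lie in [0, 1]")
  if (is.null(seed)) abort("a seed is required for simulation")
  structure(list(n_reads = as.integer(n_reads), arm5_prob = arm5_prob,
                 start_jitter = start_jitter, len5 = len5, len3 = len3,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a small-RNA read set from a mirtron hairpin
#'
#' Draws reads from the two hairpin arms with a configurable arm bias,
#' 5'-start jitter, per-arm length distribution and substitution errors.
#' 5'-arm reads start at intron position 1 (+ jitter); 3'-arm reads start at
#' the 3'-arm boundary (+ jitter), i.e. the Dicer-defined 5' end of the 3'
#' product. Reads are truncated at the intron ends. Identical parameters and
#' seed give byte-identical output.
#'
#' @param hairpin A `mirtron_hairpin`.
#' @param params A [sim_params()] object.
#' @return Tibble with `name`, `seq`, `qual` plus a `truth` attribute (list:
#'   per-arm emitted counts and intended-start counts) for oracle checks.
#'   Write with [write_fastq()] / [write_simulation()].
#' @export
simulate_reads <- function(hairpin, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  intron <- hairpin_intron(hairpin)
  L <- nchar(intron)
  L5 <- nchar(hairpin$arm5)
  start3 <- L - nchar(hairpin$arm3) + 1L # intended 5' start of the 3'-arm product
  n <- params$n_reads
  if (n == 0) {
    out <- tibble(name = character(), seq = character(), qual = character())
    attr(out, "truth") <- list(n_arm5 = 0L, n_arm3 = 0L,
                               n_intended_start5 = 0L, n_intended_start3 = 0L)
    return(out)
  }
  set.seed(params$seed)
  from5 <- runif(n) < params$arm5_prob
  jitter <- as.integer(sample(names(params$start_jitter), n, replace = TRUE,
                              prob = params$start_jitter))
  len <- integer(n)
  len[from5] <- as.integer(sample(names(params$len5), sum(from5), replace = TRUE,
                                  prob = params$len5))
  len[!from5] <- as.integer(sample(names(params$len3), sum(!from5), replace = TRUE,
                                   prob = params$len3))
  start <- ifelse(from5, 1L + jitter, start3 + jitter)
  start <- pmax(start, 1L)
  end <- pmin(start + len - 1L, L)
  seqs <- str_sub(intron, start, end)
  if (params$error_rate > 0) {
    seqs <- map_chr(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- runif(length(b)) < params$error_rate
      if (any(hit)) {
        b[hit] <- vapply(b[hit],
                         function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                         character(1))
      }
      paste(b, collapse = "")
    })
  }
  out <- tibble(
    name = sprintf("sim_%06d_%s", seq_len(n), ifelse(from5, "5p", "3p")),
    seq = seqs,
    qual = strrep("I", nchar(seqs))
  )
  attr(out, "truth") <- list(
    n_arm5 = sum(from5),
    n_arm3 = sum(!from5),
    n_intended_start5 = sum(from5 & jitter == 0L),
    n_intended_start3 = sum(!from5 & jitter == 0L),
    params = unclass(params)
  )
  out
}

#' Write simulated reads plus their ground-truth sidecar
#'
#' @param reads Tibble from [simulate_reads()].
#' @param fastq_path,truth_path Output paths (FASTQ and JSON).
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(reads, fastq_path, truth_path) {
  write_fastq(reads, fastq_path)
  jsonlite::write_json(attr(reads, "truth"), truth_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fastq_path, truth_path))
}

#' Adaptor-trim and length-filter raw small-RNA reads
#'
#' Removes the 3' sequencing adaptor (earliest position whose read suffix
#' matches an adaptor prefix of at least `min_overlap` bases) and keeps reads
#' whose trimmed length falls in the analysis window, by default 18-25 nt.
#'
#' @param reads Tibble with a `seq` column (e.g. from [read_fastq()]) or a
#'   character vector.
#' @param adaptor3 3' adaptor sequence; `NULL` skips trimming.
#' @param length_window Inclusive retained-length range (default `c(18, 25)`).
#' @param min_overlap Minimum read/adaptor overlap to trim (default 5).
#' @return Tibble of retained reads aggregated to `(seq, count)`, with
#'   attributes `n_input`, `n_trimmed`, `n_dropped`.
#' @export
trim_and_filter <- function(reads, adaptor3 = NULL,
                            length_window = c(18, 25), min_overlap = 5) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  seqs <- dna(seqs, allow_n = TRUE)
  n_input <- length(seqs)
  n_trimmed <- 0L
  if (!is.null(adaptor3)) {
    adaptor3 <- dna(adaptor3)
    if (nchar(adaptor3) == 0) abort("adaptor must be non-empty when trimming is requested")
    seqs <- map_chr(seqs, function(s) {
      L <- nchar(s)
      for (i in seq_len(max(L - min_overlap + 1, 0))) {
        o <- min(L - i + 1, nchar(adaptor3))
        if (o >= min_overlap &&
            str_sub(s, i, i + o - 1) == str_sub(adaptor3, 1, o)) {
          n_trimmed <<- n_trimmed + 1L
          return(str_sub(s, 1, i - 1))
        }
      }
      s
    })
  }
  keep <- nchar(seqs) >= length_window[1] & nchar(seqs) <= length_window[2]
  out <- tibble(seq = seqs[keep]) |>
    count(.data$seq, name = "count") |>
    arrange(desc(.data$count), .data$seq)
  attr(out, "n_input") <- n_input
  attr(out, "n_trimmed") <- n_trimmed
  attr(out, "n_dropped") <- n_input - sum(keep)
  out
}

#' Align a read set against a mirtron hairpin
#'
#' Exact (or <= `max_mismatch`) substring matching of each read against the
#' full intron. Multi-mapping reads take the leftmost hit and are flagged.
#' Arm assignment follows the read start: within the 5' arm region -> `5p`,
#' within the loop -> `loop` (excluded from arm fractions), within the 3'
#' arm -> `3p`; unaligned reads keep `NA` coordinates.
#'
#' @param readset Tibble with `seq` (and optionally `count`) columns.
#' @param hairpin A `mirtron_hairpin`.
#' @param max_mismatch Allowed mismatches (default 0, configurable up to 1).
#' @return Tibble with `seq`, `count`, `start`, `end`, `arm`, `multimap`,
#'   plus attribute `n_unaligned` (read count failing to align).
#' @export
align_reads <- function(readset, hairpin, max_mismatch = 0) {
  if (!"count" %in% names(readset)) readset$count <- 1L
  readset <- readset |>
    group_by(.data$seq) |>
    summarise(count = sum(.data$count), .groups = "drop")
  intron <- hairpin_intron(hairpin)
  L5 <- nchar(hairpin$arm5)
  loop_end <- L5 + nchar(hairpin$loop)
  subject <- Biostrings::DNAString(intron)
  hits <- map(readset$seq, function(s) {
    m <- Biostrings::matchPattern(s, subject, max.mismatch = max_mismatch)
    if (length(m) == 0) return(c(NA_integer_, NA_integer_, 0L))
    c(BiocGenerics::start(m)[1], BiocGenerics::end(m)[1], length(m))
  })
  out <- readset |>
    mutate(
      start = map_int(hits, 1),
      end = map_int(hits, 2),
      multimap = map_int(hits, 3) > 1L,
      arm = dplyr::case_when(
        is.na(.data$start) ~ NA_character_,
        .data$start <= L5 ~ "5p",
        .data$start <= loop_end ~ "loop",
        TRUE ~ "3p"
      )
    )
  attr(out, "n_unaligned") <- sum(out$count[is.na(out$start)])
  out
}

#' Summarise mirtron processing from aligned small-RNA reads
#'
#' Computes the read-level processing statistics used to validate a mirtron:
#' arm fractions (of arm-assigned reads), the guide-arm fraction, 5'-end
#' fidelity (fraction of guide-arm reads starting at the intended first
#' base), per-arm length distributions and per-position coverage across the
#' hairpin.
#'
#' @param alignments Tibble from [align_reads()].
#' @param hairpin The `mirtron_hairpin` the reads were aligned to.
#' @param intended_guide_arm `"5p"` or `"3p"`; defaults to the hairpin's own
#'   designation.
#' @return An `arm_profile` object. `glance()` gives the one-row summary,
#'   `tidy()` the per-position incidence table; zero aligned reads yield an
#'   explicit empty profile (`status = "empty"`), not an error.
#' @export
arm_profile <- function(alignments, hairpin,
                        intended_guide_arm = hairpin$guide_arm) {
  intron <- hairpin_intron(hairpin)
  L <- nchar(intron)
  L5 <- nchar(hairpin$arm5)
  start3 <- L - nchar(hairpin$arm3) + 1L
  aligned <- filter(alignments, !is.na(.data$start))
  total_aligned <- sum(aligned$count)
  bases <- strsplit(intron, "")[[1]]
  region <- c(rep("arm5", L5), rep("loop", nchar(hairpin$loop)),
              rep("arm3", nchar(hairpin$arm3)))
  incidence <- integer(L)
  for (i in seq_len(nrow(aligned))) {
    rng <- aligned$start[i]:aligned$end[i]
    incidence[rng] <- incidence[rng] + aligned$count[i]
  }
  per_position <- tibble(position = seq_len(L), base = bases,
                         region = region, incidence = incidence)
  if (total_aligned == 0) {
    return(structure(list(
      status = "empty", total_reads = sum(alignments$count),
      total_aligned = 0L, arm5_reads = 0L, arm3_reads = 0L,
      arm5_fraction = NA_real_, arm3_fraction = NA_real_,
      guide_fraction = NA_real_, five_prime_fidelity = NA_real_,
      intended_guide_arm = intended_guide_arm,
      length_histogram = tibble(arm = character(), length = integer(),
                                count = integer()),
      per_position = per_position
    ), class = "arm_profile"))
  }
  arm_reads <- aligned |>
    filter(.data$arm %in% c("5p", "3p")) |>
    group_by(.data$arm) |>
    summarise(count = sum(.data$count), .groups = "drop")
  n5 <- sum(arm_reads$count[arm_reads$arm == "5p"])
  n3 <- sum(arm_reads$count[arm_reads$arm == "3p"])
  guide_reads <- filter(aligned, .data$arm == intended_guide_arm)
  intended_start <- if (intended_guide_arm == "5p") 1L else start3
  fid <- if (sum(guide_reads$count) > 0) {
    sum(guide_reads$count[guide_reads$start == intended_start]) /
      sum(guide_reads$count)
  } else NA_real_
  len_hist <- aligned |>
    filter(.data$arm %in% c("5p", "3p")) |>
    mutate(length = .data$end - .data$start + 1L) |>
    group_by(.data$arm, .data$length) |>
    summarise(count = sum(.data$count), .groups = "drop")
  structure(list(
    status = "ok",
    total_reads = sum(alignments$count),
    total_aligned = total_aligned,
    arm5_reads = n5, arm3_reads = n3,
    arm5_fraction = if (n5 + n3 > 0) n5 / (n5 + n3) else NA_real_,
    arm3_fraction = if (n5 + n3 > 0) n3 / (n5 + n3) else NA_real_,
    guide_fraction = if (n5 + n3 > 0) {
      (if (intended_guide_arm == "5p") n5 else n3) / (n5 + n3)
    } else NA_real_,
    five_prime_fidelity = fid,
    intended_guide_arm = intended_guide_arm,
    length_histogram = len_hist,
    per_position = per_position
  ), class = "arm_profile")
}

#' @export
print.arm_profile <- function(x, ...) {
  if (x$status == "empty") {
    cat("<arm_profile> empty: no reads aligned\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<arm_profile> %d aligned reads: %.1f%% 5' arm / %.1f%% 3' arm; guide (%s) %.1f%%, 5'-end fidelity %.1f%%\n",
    x$total_aligned, 100 * x$arm5_fraction, 100 * x$arm3_fraction,
    x$intended_guide_arm, 100 * x$guide_fraction,
    100 * x$five_prime_fidelity))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arm_profile <- function(x, ...) x$per_position

#' @exportS3Method generics::glance
glance.arm_profile <- function(x, ...) {
  modal_len <- function(arm) {
    h <- filter(x$length_histogram, .data$arm == !!arm)
    if (nrow(h) == 0) return(NA_integer_)
    h$length[which.max(h$count)]
  }
  tibble(
    status = x$status,
    total_reads = x$total_reads,
    total_aligned = x$total_aligned,
    arm5_reads = x$arm5_reads, arm3_reads = x$arm3_reads,
    arm5_fraction = x$arm5_fraction, arm3_fraction = x$arm3_fraction,
    guide_fraction = x$guide_fraction,
    five_prime_fidelity = x$five_prime_fidelity,
    modal_length_5p = modal_len("5p"),
    modal_length_3p = modal_len("3p")
  )
}
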