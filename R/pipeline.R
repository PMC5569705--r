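#' Configuration for the knockdown-replacement design pipeline
#'
#' Collects every tunable the pipeline uses so that a report always embeds
#' the exact configuration that produced it.
#'
#' @param guide_length Mature guide length (default 21).
#' @param arm Arm(s) considered for the guide.
#' @param target_weights Composite weights for target scoring
#'   (see [score_targets()]).
#' @param site_weights Composite weights for insertion-site ranking
#'   (see [find_insertion_sites()]).
#' @param seed_positions Guide positions treated as the seed.
#' @param min_total,min_seed Resistance-verification thresholds.
#' @param max_mismatch Mismatch allowance for specificity search.
#' @param backbone A [backbone_spec()].
#' @param hexamers ESE hexamer set (default: packaged toy set).
#' @param usage Codon usage table (default: packaged human table).
#' @param seed RNG seed recorded with the run.
#' @return A `kr_config` list.
#' @export
kr_config <- function(guide_length = 21,
                      arm = c("both", "5p", "3p"),
                      target_weights = c(donor = 0.4, ppt = 0.4, end_bias = 0.2),
                      site_weights = c(consensus = 0.5, ese = 0.2,
                                       first_exon = 0.2, dist3 = 0.1),
                      seed_positions = 2:8,
                      min_total = 4, min_seed = 2,
                      max_mismatch = 2,
                      backbone = backbone_spec(),
                      hexamers = read_hexamers(system.file(
                        "extdata", "ese_toy.txt", package = "mirtronkr")),
                      usage = read_codon_usage(),
                      seed = 1L) {
  structure(list(
    guide_length = as.integer(guide_length), arm = match.arg(arm),
    target_weights = target_weights, site_weights = site_weights,
    seed_positions = seed_positions, min_total = min_total,
    min_seed = min_seed, max_mismatch = max_mismatch, backbone = backbone,
    hexamers = hexamers, usage = usage, seed = as.integer(seed)
  ), class = "kr_config")
}

#' Run the full knockdown-replacement design pipeline
#'
#' Chains the package end to end: scan the target transcript for
#' splice-compatible sites, score and rank them, design a mirtron hairpin
#' (plus unspliceable and shRNA control variants) for the top site, rank
#' candidate insertion junctions in the replacement transgene, recode the
#' transgene over the target window for RNAi resistance, verify resistance,
#' and audit the recoded region for newly created splice signals.
#' Deterministic given inputs and configuration.
#'
#' @param transcript Target transcript: tibble with `name`/`seq`, character
#'   string, or FASTA path.
#' @param transgene_cds Replacement-gene CDS (same accepted forms).
#' @param config A [kr_config()].
#' @param transcriptome Optional tibble/character set of transcripts for the
#'   specificity screen.
#' @return A `kr_report` list with elements `targets`, `hairpin`,
#'   `variants` (us, shrna), `insertion_sites`, `recoding`, `resistance`,
#'   `audit`, `warnings`, `config`.
#' @export
run_kr_pipeline <- function(transcript, transgene_cds, config = kr_config(),
                            transcriptome = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  as_single_seq <- function(x, what) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) x <- read_fasta(x)
    tx <- as_seq_tbl(x)
    if (nrow(tx) == 0) abort(sprintf("no %s sequence supplied", what))
    tx[1, ]
  }
  tx <- stage("input", as_single_seq(transcript, "transcript"))
  tg <- stage("input", as_single_seq(transgene_cds, "transgene"))
  warnings <- character()

  targets <- stage("scan", {
    s <- scan_targets(tx, guide_length = config$guide_length, arm = config$arm)
    s <- score_targets(s, weights = config$target_weights)
    if (nrow(s) > 0) rank_targets(s) else s
  })
  if (!is.null(transcriptome) && nrow(targets) > 0) {
    targets <- stage("specificity", specificity_counts(
      targets, transcriptome, max_mismatch = config$max_mismatch,
      seed = config$seed_positions))
  }

  hairpin <- NULL; variants <- list(); recoding <- NULL
  resistance <- NULL; audit <- NULL; insertion_sites <- NULL
  if (nrow(targets) == 0) {
    warnings <- c(warnings, "no splice-compatible target windows found on the transcript")
  } else {
    top <- targets[1, ]
    hairpin <- stage("design", build_hairpin(top$guide, arm = top$arm,
                                             backbone = config$backbone))
    variants <- stage("variants", list(
      us = make_unspliceable(hairpin),
      shrna = to_shrna(hairpin)
    ))
  }
  insertion_sites <- stage("sites", find_insertion_sites(
    tg$seq, hexamers = config$hexamers, weights = config$site_weights))
  if (nrow(insertion_sites) == 0) {
    warnings <- c(warnings, "no AG-terminated junctions in the transgene")
  }

  if (!is.null(hairpin)) {
    top <- targets[1, ]
    hit <- str_locate_all(tg$seq, stringr::fixed(top$window))[[1]]
    if (nrow(hit) == 0) {
      warnings <- c(warnings,
                    "target window absent from the transgene; recoding skipped")
    } else {
      interval <- c(hit[1, 1], hit[1, 2])
      recoding <- stage("recode", recode(tg$seq, interval, usage = config$usage))
      resistance <- stage("verify", verify_resistance(
        recoding$recoded_region, top$guide,
        min_total = config$min_total, min_seed = config$min_seed,
        seed = config$seed_positions))
      flank <- 20L
      lo <- max(1, interval[1] - flank)
      hi <- min(nchar(tg$seq), interval[2] + flank)
      audit <- stage("audit", audit_new_signals(
        str_sub(recoding$original, lo, hi),
        str_sub(recoding$recoded, lo, hi),
        hexamers = config$hexamers))
      if (!resistance$pass) {
        warnings <- c(warnings, "recoded target fails the resistance thresholds")
      }
    }
  }
  structure(list(
    transcript = tx$name, transgene = tg$name,
    targets = targets, hairpin = hairpin, variants = variants,
    insertion_sites = insertion_sites, recoding = recoding,
    resistance = resistance, audit = audit,
    warnings = warnings, config = config
  ), class = "kr_report")
}

#' @export
print.kr_report <- function(x, ...) {
  cat(sprintf("<kr_report> transcript %s -> transgene %s\n", x$transcript, x$transgene))
  cat(sprintf("  targets: %d candidate site(s)\n", nrow(x$targets)))
  if (!is.null(x$hairpin)) {
    cat(sprintf("  hairpin: guide %s (%s arm), dG %.2f kcal/mol\n",
                x$hairpin$guide, x$hairpin$guide_arm, x$hairpin$thermo$delta_g))
  }
  cat(sprintf("  insertion sites: %d junction(s)\n", nrow(x$insertion_sites)))
  if (!is.null(x$resistance)) {
    cat(sprintf("  resistance: %d total / %d seed mismatches -> %s\n",
                x$resistance$total_mismatches, x$resistance$seed_mismatches,
                if (x$resistance$pass) "pass" else "FAIL"))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.kr_report <- function(x, ...) {
  tibble(
    n_targets = nrow(x$targets),
    top_guide = if (nrow(x$targets)) x$targets$guide[1] else NA_character_,
    top_arm = if (nrow(x$targets)) x$targets$arm[1] else NA_character_,
    hairpin_delta_g = if (!is.null(x$hairpin)) x$hairpin$thermo$delta_g else NA_real_,
    n_insertion_sites = nrow(x$insertion_sites),
    top_junction = if (nrow(x$insertion_sites)) x$insertion_sites$cds_position[1] else NA_integer_,
    nt_changes = if (!is.null(x$recoding)) x$recoding$nt_changes else NA_integer_,
    resistance_pass = if (!is.null(x$resistance)) x$resistance$pass else NA,
    n_warnings = length(x$warnings)
  )
}
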