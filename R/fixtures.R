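#' Generate a reproducible synthetic fixture set for the KR workflow
#'
#' Writes a self-consistent set of small synthetic inputs: a target
#' transcript (equal to the replacement-gene CDS, the knockdown-replacement
#' situation) with a planted 5'-arm-compatible target window, a CAAG|G
#' insertion junction backed by an ESE hexamer, a toy ESE set, a toy codon
#' usage table, and a simulated small-RNA library (FASTQ plus ground-truth
#' JSON) for the planted guide's hairpin. Identical seeds give
#' byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_reads Reads in the simulated library (default 2000).
#' @return Invisibly, a tibble of the written files with their roles.
#' @export
generate_fixtures <- function(dir, seed = 1L, n_reads = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  safe_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))
  n_codons <- 200L
  codons <- sample(safe_codons, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  # planted insertion junction: ...C AAG | G... at CDS position 121
  codons[40] <- "CAA"; codons[41] <- "GGA"
  # ESE hexamer GAAGAA starting at junction offset +6
  codons[43] <- "GAA"; codons[44] <- "GAA"
  # planted in-frame target window (ends AC so the guide starts GT), codons 101-107
  planted_window <- c("GAA", "GAC", "AAT", "TCT", "AAT", "ACA", "TAC")
  codons[101:107] <- planted_window
  planted <- list(
    window_start = 301L, window_end = 321L,
    junction = 121L, ese_offset = 6L
  )
  protected <- c(40:44, 101:107)
  cds <- paste(codons, collapse = "")
  # scrub accidental junction/ESE motifs outside the planted regions so the
  # planted junction dominates the ranking deterministically
  for (pass in 1:50) {
    occ <- rbind(str_locate_all(cds, "CAAGG")[[1]],
                 str_locate_all(cds, "GAAGAA")[[1]])
    occ <- occ[!(occ[, 1] >= 118 & occ[, 1] <= 132) &
                 !(occ[, 1] >= 295 & occ[, 1] <= 327), , drop = FALSE]
    if (nrow(occ) == 0) break
    ci <- (occ[1, 1] - 1) %/% 3 + 1
    ci <- setdiff(ci + 0:1, protected)[1]
    codons[ci] <- sample(setdiff(safe_codons, codons[ci]), 1)
    cds <- paste(codons, collapse = "")
  }
  window <- str_sub(cds, planted$window_start, planted$window_end)
  guide <- revcomp(window)

  tx_path <- file.path(dir, "transcript.fasta")
  tg_path <- file.path(dir, "transgene.fasta")
  write_fasta(tibble(name = "synthetic_transcript", seq = cds), tx_path)
  write_fasta(tibble(name = "synthetic_transgene", seq = cds), tg_path)

  ese_path <- file.path(dir, "ese_toy.txt")
  file.copy(system.file("extdata", "ese_toy.txt", package = "mirtronkr"),
            ese_path, overwrite = TRUE)

  usage_path <- file.path(dir, "codon_usage_toy.tsv")
  writeLines(c(
    "# toy codon usage table (synthetic fractions for tests)",
    "codon\taa\tfraction",
    "TTT\tF\t0.45", "TTC\tF\t0.55",
    "CTG\tL\t0.60", "CTC\tL\t0.40",
    "GAA\tE\t0.42", "GAG\tE\t0.58",
    "AAA\tK\t0.43", "AAG\tK\t0.57",
    "GAT\tD\t0.46", "GAC\tD\t0.54",
    "AAT\tN\t0.47", "AAC\tN\t0.53",
    "TCT\tS\t0.50", "AGC\tS\t0.50",
    "ACA\tT\t0.50", "ACC\tT\t0.50",
    "TAT\tY\t0.44", "TAC\tY\t0.56",
    "ATG\tM\t1.00", "TGG\tW\t1.00"
  ), usage_path)

  hp <- build_hairpin(guide, arm = "5p")
  reads <- simulate_reads(hp, sim_params(n_reads = n_reads,
                                         seed = seed + 1000L))
  fq_path <- file.path(dir, "reads.fastq")
  truth_path <- file.path(dir, "reads_truth.json")
  write_simulation(reads, fq_path, truth_path)

  manifest <- tibble(
    file = c(tx_path, tg_path, ese_path, usage_path, fq_path, truth_path),
    role = c("target transcript", "replacement transgene CDS",
             "toy ESE hexamer set", "toy codon usage table",
             "simulated small-RNA reads", "simulation ground truth")
  )
  attr(manifest, "planted") <- c(planted, list(window = window, guide = guide))
  invisible(manifest)
}
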