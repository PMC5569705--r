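# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and Biostrings) so that agreement is a
# genuine two-route check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# character-wise complement map, then reversal
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

# codon-by-codon dictionary lookup translation
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# O(n^2) enumeration of every run of `base` starting at every position
oracle_longest_run <- function(seq, base) {
  b <- strsplit(seq, "")[[1]]
  best_len <- 0L; best_start <- NA_integer_
  for (s in seq_along(b)) {
    if (b[s] != base) next
    len <- 0L
    while (s + len <= length(b) && b[s + len] == base) len <- len + 1L
    if (len > best_len) { best_len <- len; best_start <- s }
  }
  list(run_length = best_len, start = best_start)
}

# brute-force check of the two arm rules over every window
oracle_scan_windows <- function(seq, guide_len) {
  L <- nchar(seq)
  out <- list()
  if (L >= guide_len) {
    for (s in seq_len(L - guide_len + 1)) {
      w <- substr(seq, s, s + guide_len - 1)
      if (substr(w, guide_len - 1, guide_len) == "AC") {
        out[[length(out) + 1]] <- data.frame(start = s, arm = "5p", window = w)
      }
      if (substr(w, 1, 2) == "CT") {
        out[[length(out) + 1]] <- data.frame(start = s, arm = "3p", window = w)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), arm = character(), window = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$arm), ]
}

# direct substring placement over the signed ESE window
oracle_scan_ese <- function(up, down, hexamers, window = c(5, 10)) {
  full <- paste0(up, down)
  nu <- nchar(up)
  hits <- list()
  for (o in c(-(window[2]:window[1]), window[1]:window[2])) {
    idx <- if (o < 0) nu + o + 1 else nu + o
    if (idx < 1 || idx + 5 > nchar(full)) next
    h <- substr(full, idx, idx + 5)
    if (h %in% hexamers) {
      hits[[length(hits) + 1]] <- data.frame(hexamer = h, offset = o)
    }
  }
  if (length(hits) == 0) return(data.frame(hexamer = character(), offset = integer()))
  df <- do.call(rbind, hits)
  df[order(df$offset), ]
}

# random guide satisfying an arm rule
random_guide <- function(arm, len = 21) {
  if (arm == "5p") paste0("GT", random_dna(len - 2))
  else paste0(random_dna(len - 2), "AG")
}

# bare hairpin from two explicit arms (bypasses passenger design)
new_test_hairpin <- function(arm5, arm3, loop = "TAGTGAAGCCACAGATGTA") {
  mirtronkr:::new_hairpin(arm5, loop, arm3, guide = arm5, guide_arm = "5p",
                          backbone = backbone_spec(loop = loop))
}

# independent re-summation of the packaged nearest-neighbor table over an
# explicit pairing table (duplicate of the estimator's contract, written
# against the documented rules rather than the implementation)
oracle_delta_g <- function(pairing) {
  stack_tab <- c(
    "AU.AU" = -0.93, "AU.UA" = -1.10, "AU.GC" = -2.08, "AU.CG" = -2.24,
    "UA.AU" = -1.33, "UA.UA" = -0.93, "UA.GC" = -2.11, "UA.CG" = -2.35,
    "GC.AU" = -2.35, "GC.UA" = -2.24, "GC.GC" = -3.26, "GC.CG" = -3.42,
    "CG.AU" = -2.11, "CG.UA" = -2.08, "CG.GC" = -2.36, "CG.CG" = -3.26)
  dg <- 5.6 + 0.8 * sum(pairing$class == "mismatch")
  for (i in seq_len(nrow(pairing) - 1)) {
    c1 <- pairing$class[i]; c2 <- pairing$class[i + 1]
    if (c1 == "mismatch" || c2 == "mismatch") next
    if (c1 == "WC" && c2 == "WC") {
      key <- paste0(chartr("T", "U", paste0(pairing$base5[i], pairing$base3[i])),
                    ".",
                    chartr("T", "U", paste0(pairing$base5[i + 1], pairing$base3[i + 1])))
      dg <- dg + stack_tab[[key]]
    } else {
      dg <- dg - 0.5
    }
  }
  dg
}
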