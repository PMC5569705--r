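toy_usage <- function() {
  tibble::tibble(
    codon = c("CTG", "CTC", "ATG", "GAA", "GAG", "AAA", "AAG", "TGG"),
    aa = c("L", "L", "M", "E", "E", "K", "K", "W"),
    fraction = c(0.6, 0.4, 1, 0.42, 0.58, 0.43, 0.57, 1)
  )
}

random_cds <- function(n_codons) {
  safe <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(sample(safe, n_codons, replace = TRUE), collapse = "")
}

test_that("recode preserves the protein and counts changes as Hamming distance", {
  set.seed(51)
  usage <- read_codon_usage()
  for (i in 1:100) {
    cds <- random_cds(sample(10:20, 1))
    L <- nchar(cds)
    iv <- sort(sample(seq_len(L), 2))
    rc <- recode(cds, iv, usage = usage)
    expect_equal(translate_cds(rc$recoded), translate_cds(cds))
    expect_equal(nchar(rc$recoded), nchar(cds))
    a <- strsplit(cds, "")[[1]]; b <- strsplit(rc$recoded, "")[[1]]
    expect_equal(rc$nt_changes, sum(a != b))
    # changes confined to codons overlapping the interval
    changed <- which(a != b)
    if (length(changed)) {
      expect_true(all(changed >= iv[1] - 2 & changed <= iv[2] + 2))
    }
  }
})

test_that("all-Met regions cannot be recoded and warn instead", {
  rc <- recode(strrep("ATG", 5), c(1, 15), usage = toy_usage())
  expect_equal(rc$nt_changes, 0L)
  expect_true(any(grepl("no synonymous alternative", rc$warnings)))
})

test_that("stop codons inside the interval are never altered", {
  cds <- paste0("ATGGAATAA")
  rc <- recode(cds, c(1, 9), usage = toy_usage())
  expect_equal(substr(rc$recoded, 7, 9), "TAA")
  expect_true(any(grepl("stop codon", rc$warnings)))
})

test_that("codon choice maximises nt differences, tie-broken by closest usage", {
  # Leu under the full table: CTA -> TTG is one of the 2-difference options;
  # verify against exhaustive enumeration of synonyms
  usage <- read_codon_usage()
  code <- Biostrings::GENETIC_CODE
  set.seed(52)
  for (i in 1:20) {
    cds <- random_cds(1)
    aa <- unname(code[cds])
    rc <- recode(cds, c(1, 3), usage = usage)
    syn <- setdiff(names(code)[code == aa], cds)
    if (length(syn) == 0) { expect_equal(rc$nt_changes, 0L); next }
    uf <- setNames(usage$fraction, usage$codon)
    floor_ok <- syn[uf[syn] >= 0.05]
    if (length(floor_ok)) syn <- floor_ok
    dmax <- max(vapply(syn, function(s)
      sum(strsplit(s, "")[[1]] != strsplit(cds, "")[[1]]), integer(1)))
    expect_equal(rc$nt_changes, dmax)
    best <- syn[vapply(syn, function(s)
      sum(strsplit(s, "")[[1]] != strsplit(cds, "")[[1]]), integer(1)) == dmax]
    gap <- abs(uf[best] - uf[cds])
    expect_equal(unname(abs(uf[rc$changes$new] - uf[cds])), min(gap))
  }
})

test_that("recoding only ever adds guide mismatches and never recreates the target", {
  set.seed(53)
  usage <- read_codon_usage()
  for (i in 1:15) {
    cds <- random_cds(15)
    iv <- c(10, 30)
    guide <- revcomp(substr(cds, iv[1], iv[2]))
    m0 <- verify_resistance(substr(cds, iv[1], iv[2]), guide)$total_mismatches
    expect_equal(m0, 0L) # the unmodified target pairs the guide perfectly
    r1 <- recode(cds, iv, usage = usage)
    m1 <- verify_resistance(r1$recoded_region, guide)$total_mismatches
    expect_gte(m1, m0)
    if (r1$nt_changes > 0) expect_gt(m1, 0)
    # re-recoding with the same configuration never hands back the exact
    # original target region
    r2 <- recode(r1$recoded, iv, usage = usage)
    expect_false(r2$recoded_region == r1$original_region)
  }
})

test_that("verify_resistance counts total and seed mismatches positionwise", {
  guide <- paste0(random_dna(19), "AG")
  target <- oracle_revcomp(guide)
  # unmodified target: zero mismatches, fail
  v0 <- verify_resistance(target, guide)
  expect_equal(v0$total_mismatches, 0L)
  expect_false(v0$pass)
  # plant six mismatches, three inside the seed-complementary block
  tb <- strsplit(target, "")[[1]]
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
  Lg <- nchar(guide)
  pos <- c(Lg - c(2, 4, 6) + 1, 1, 2, 3) # guide pos 2,4,6 are seed; 19,20,21 not
  for (p in pos) tb[p] <- flip(tb[p])
  v <- verify_resistance(paste(tb, collapse = ""), guide)
  expect_equal(v$total_mismatches, 6L)
  expect_equal(v$seed_mismatches, 3L)
  expect_true(v$pass)
  # degenerate thresholds always pass
  expect_true(verify_resistance(target, guide, min_total = 0, min_seed = 0)$pass)
  # best-offset alignment inside a longer region
  region <- paste0("CCCCC", paste(tb, collapse = ""), "CCCCC")
  expect_equal(verify_resistance(region, guide)$offset, 6L)
})

test_that("audit_new_signals flags created donors and counts ESE deltas", {
  orig <- strrep("C", 40)
  mod <- paste0(strrep("C", 10), "GTAAGT", strrep("C", 24))
  aud <- audit_new_signals(orig, mod)
  expect_equal(aud$donor_warnings$position, 11L)
  expect_equal(aud$donor_warnings$mismatch_count, 0L)
  # identity recoding: silence
  quiet <- audit_new_signals(orig, orig, hexamers = "GAAGAA")
  expect_equal(nrow(quiet$donor_warnings), 0L)
  expect_equal(nrow(quiet$acceptor_warnings), 0L)
  expect_equal(quiet$ese_delta, 0L)
  # ESE delta equals brute-force before/after occurrence counting
  set.seed(54)
  for (i in 1:10) {
    a <- random_dna(60); b <- random_dna(60)
    count6 <- function(x, h) {
      n <- 0L
      for (s in seq_len(nchar(x) - 5)) if (substr(x, s, s + 5) == h) n <- n + 1L
      n
    }
    aud <- audit_new_signals(a, b, hexamers = "GAAGAA")
    expect_equal(aud$ese_delta, count6(b, "GAAGAA") - count6(a, "GAAGAA"))
  }
  # created acceptor context (pyrimidine tract ending AG) is flagged
  acc <- paste0(strrep("C", 20), "TTTTTTTTTTCAG", strrep("C", 7))
  aud2 <- audit_new_signals(strrep("C", 40), acc)
  expect_true(nrow(aud2$acceptor_warnings) >= 1)
})
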