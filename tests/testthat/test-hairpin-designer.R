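test_that("built hairpins satisfy the mirtron framing contract", {
  set.seed(41)
  for (arm in c("5p", "3p")) {
    for (i in 1:50) {
      g <- random_guide(arm)
      hp <- build_hairpin(g, arm = arm)
      intron <- hairpin_intron(hp)
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      # guide preserved byte-identical, both arms at guide length
      expect_identical(hairpin_guide_arm(hp), g)
      expect_equal(nchar(hp$arm5), 21L)
      expect_equal(nchar(hp$arm3), 21L)
    }
  }
})

test_that("arm-rule violations are rejected with a named terminus", {
  expect_error(build_hairpin(paste0("AT", random_dna(19)), arm = "5p"), "start GT")
  expect_error(build_hairpin(paste0(random_dna(19), "AT"), arm = "3p"), "end AG")
})

test_that("design_passenger minimises polypyrimidine interruptions on 5p-guide hairpins", {
  set.seed(42)
  # a guide whose complement already yields a purine-free tract is untouched
  # (apart from the enforced acceptor AG terminus)
  clean <- paste0("GT", strrep("A", 16), "CGT")
  d <- design_passenger(clean, "5p")
  expect_true(all(d$edits$reason == "acceptor AG terminus"))
  # guides forcing purines into the tract: interruption count strictly drops
  for (i in 1:20) {
    g <- paste0("GT", random_dna(19))
    L <- nchar(g)
    before <- purine_count(oracle_revcomp(g), L - 12, L - 3)
    if (before == 0) next
    d <- design_passenger(g, "5p")
    after <- purine_count(d$passenger, L - 12, L - 3)
    expect_lt(after, before)
    expect_equal(after, 0L) # nothing in the tract is WC-protected at 21 nt
  }
})

test_that("guide 3'-terminal block stays Watson-Crick paired on 5p-guide hairpins", {
  set.seed(43)
  for (i in 1:50) {
    hp <- build_hairpin(random_guide("5p"), arm = "5p")
    terminal <- hp$pairing[hp$pairing$i5 > 21 - 4, ]
    expect_true(all(terminal$class == "WC"))
  }
})

test_that("3p-guide hairpins report the donor/WC conflict instead of hiding it", {
  g <- random_guide("3p")
  hp <- build_hairpin(g, arm = "3p")
  # the forced donor G cannot WC-pair the guide's terminal G
  expect_true(any(grepl("splice-site constraint", hp$warnings)))
  expect_identical(hairpin_guide_arm(hp), g)
})

test_that("pairing free energy equals an independent re-summation of the table", {
  set.seed(44)
  for (i in 1:20) {
    arm <- sample(c("5p", "3p"), 1)
    hp <- build_hairpin(random_guide(arm), arm = arm)
    expect_equal(hp$thermo$delta_g, oracle_delta_g(hp$pairing))
  }
})

test_that("free-energy estimator orders motifs sensibly", {
  # perfect GC duplex more negative than perfect AT duplex with the same loop
  gc <- new_test_hairpin(strrep("G", 10), strrep("C", 10))
  at <- new_test_hairpin(strrep("A", 10), strrep("T", 10))
  expect_lt(gc$thermo$delta_g, at$thermo$delta_g)
  # converting one WC pair to a mismatch is strictly destabilising
  g <- random_guide("5p")
  hp <- build_hairpin(g, arm = "5p")
  v <- destabilize(hp, n_substitutions = 1)[[1]]
  expect_gt(v$thermo$delta_g, hp$thermo$delta_g)
})

test_that("destabilize raises delta_g, keeps the guide, and sorts variants", {
  set.seed(45)
  for (i in 1:10) {
    g <- random_guide("5p")
    hp <- build_hairpin(g, arm = "5p")
    vs <- destabilize(hp, n_substitutions = 1:3)
    dgs <- vapply(vs, function(v) v$thermo$delta_g, numeric(1))
    expect_true(all(dgs > hp$thermo$delta_g))
    expect_equal(dgs, sort(dgs))
    for (v in vs) {
      expect_identical(hairpin_guide_arm(v), g)
      intron <- hairpin_intron(v)
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
  hp <- build_hairpin(random_guide("5p"), arm = "5p")
  expect_identical(destabilize(hp, n_substitutions = 0)[[1]], hp)
  expect_error(destabilize(hp, n_substitutions = 50), "editable")
})

test_that("unspliceable variants differ by exactly one G-to-A in the donor", {
  set.seed(46)
  for (i in 1:10) {
    hp <- build_hairpin(random_guide("5p"), arm = "5p")
    us <- make_unspliceable(hp)
    a <- strsplit(hairpin_intron(hp), "")[[1]]
    b <- strsplit(hairpin_intron(us), "")[[1]]
    diff <- which(a != b)
    expect_length(diff, 1)
    expect_lte(diff, 6)
    expect_equal(a[diff], "G")
    expect_equal(b[diff], "A")
    expect_true(us$unspliceable)
    # the same position cannot be substituted twice: no G remains there
    expect_error(make_unspliceable(us, position = diff), "not G")
  }
  expect_error(make_unspliceable(build_hairpin(random_guide("5p"), "5p"),
                                 position = 9), "1-6")
})

test_that("shRNA conversion swaps the final two bases for the terminator", {
  hp <- build_hairpin("GTGAGACTTCATCAGGGGTTA", arm = "5p")
  intron <- hairpin_intron(hp)
  sh <- to_shrna(hp)
  expect_equal(sh, paste0(substr(intron, 1, nchar(intron) - 2), "TTTTTT"))
  set.seed(47)
  for (i in 1:20) {
    arm <- sample(c("5p", "3p"), 1)
    hp <- build_hairpin(random_guide(arm), arm = arm)
    expect_equal(nchar(to_shrna(hp)), nchar(hairpin_intron(hp)) - 2 + 6)
  }
  # degenerate empty motif truncates by two
  expect_equal(nchar(to_shrna(hp, terminator = "")),
               nchar(hairpin_intron(hp)) - 2)
})

test_that("internal estimator rank-agrees with RNAfold on a hairpin panel", {
  set.seed(421)
  dgs <- mfe <- numeric(20)
  for (i in 1:20) {
    hp <- build_hairpin(paste0("GT", random_dna(19)), arm = "5p")
    dgs[i] <- hp$thermo$delta_g
    rna <- chartr("T", "U", hairpin_intron(hp))
    out <- system(sprintf("echo %s | RNAfold --noPS", rna), intern = TRUE)[2]
    mfe[i] <- as.numeric(gsub("[() ]", "", sub("^[.()]+\\s+", "", out)))
  }
  expect_gt(stats::cor(dgs, mfe, method = "spearman"), 0.8)
})
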