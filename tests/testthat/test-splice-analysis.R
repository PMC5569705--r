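test_that("score_donor equals Hamming distance to GTAAGT over all 4096 hexamers", {
  bases <- c("A", "C", "G", "T")
  all_hex <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases, bases))
  sc <- score_donor(all_hex)
  cons <- strsplit("GTAAGT", "")[[1]]
  ham <- vapply(all_hex, function(h) sum(strsplit(h, "")[[1]] != cons), integer(1))
  expect_equal(sc$mismatch_count, unname(ham))
  expect_equal(sc$mismatch_count, lengths(sc$mismatch_positions))
  expect_true(all(unlist(sc$mismatch_positions) %in% 1:6))
})

test_that("score_donor reproduces the published weak-donor examples", {
  expect_equal(score_donor("GTGAGA")$mismatch_count, 2L)
  expect_equal(score_donor("GTAAGT")$mismatch_count, 0L)
  expect_equal(score_donor("GTGGGT")$mismatch_positions[[1]], c(3L, 4L))
  expect_error(score_donor("GTAAG"), "6 nt")
})

test_that("score_donor PWM mode sums per-position weights", {
  pwm <- matrix(0.1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["G", 1] <- 0.9; pwm["T", 2] <- 0.9
  sc <- score_donor(c("GTAAGT", "ATAAGT"), pwm = pwm)
  expect_equal(sc$pwm_score[1] - sc$pwm_score[2], 0.8)
})

test_that("score_acceptor requires terminal AG and scores tract purity", {
  a <- score_acceptor("GTTCTTCTTTCAG")
  expect_true(a$valid)
  expect_equal(a$ppt_interruptions, 1L)
  b <- score_acceptor("TTTTTTTTTTCAG")
  expect_equal(b$ppt_interruptions, 0L)
  expect_equal(b$ppt_purity, 1)
  expect_gt(b$acceptor_score, a$acceptor_score)
  bad <- score_acceptor("TTTTTTTTTTCAT")
  expect_false(bad$valid)
  expect_equal(bad$acceptor_score, 0)
  # CAG outranks TAG at equal tract
  expect_gt(score_acceptor("TTTTTTTTTTCAG")$acceptor_score,
            score_acceptor("TTTTTTTTTTTAG")$acceptor_score)
  expect_error(score_acceptor("TTTCAG"), "13 nt")
})

test_that("find_g_triplets finds all runs >= 3 with donor-proximity flags", {
  fx <- mirt1cN_synthetic()$seq
  g <- find_g_triplets(fx)
  expect_true(any(g$start == 15 & g$run_length == 4))
  expect_true(g$donor_proximal[g$start == 15])
  expect_equal(nrow(find_g_triplets("ACTACTACT")), 0L)
  set.seed(31)
  for (i in 1:20) {
    x <- random_dna(80)
    got <- find_g_triplets(x)
    # manual scan of all maximal runs
    r <- rle(strsplit(x, "")[[1]])
    starts <- cumsum(c(1, r$lengths))
    want <- which(r$values == "G" & r$lengths >= 3)
    expect_equal(got$start, as.integer(starts[want]))
    expect_equal(got$run_length, as.integer(r$lengths[want]))
  }
})

test_that("find_branch_point scans YTNAY in the 15-45 nt window", {
  intron <- paste0(strrep("G", 32), "CTAAC", strrep("T", 20), "CAG")
  bp <- find_branch_point(intron)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$start, 33L)
  expect_equal(bp$branch_a, 36L)
  expect_equal(nrow(find_branch_point(strrep("G", 60))), 0L)
  expect_equal(nrow(find_branch_point("ACGTACGT")), 0L) # too short
  # tie-break towards the 3' end
  intron2 <- paste0(strrep("G", 10), "CTAAC", strrep("G", 5), "CTAAC",
                    strrep("T", 20), "CAG")
  bp2 <- find_branch_point(intron2)
  expect_equal(bp2$start, 21L)
})

test_that("scan_ese is equivalent to brute-force substring placement", {
  up <- paste0(strrep("C", 14), "GAAGAA")      # starts at offset -6
  down <- paste0("TTTT", "GAAGAA", strrep("C", 10)) # starts at offset +5
  hits <- scan_ese(up, down, "GAAGAA")
  expect_equal(hits$offset, c(-6L, 5L))
  expect_equal(hits$side, c("up", "down"))
  # +4 is outside the window
  down4 <- paste0("TTT", "GAAGAA", strrep("C", 11))
  expect_equal(nrow(scan_ese(up = strrep("C", 20), down4, "GAAGAA")), 0L)
  expect_equal(nrow(scan_ese(strrep("C", 20), strrep("C", 20), "GAAGAA")), 0L)
  expect_error(scan_ese(up, down, character(0)), "empty")
  set.seed(32)
  toyset <- c("GAAGAA", "TGGAAG", "CAGAAG")
  for (i in 1:25) {
    u <- random_dna(20); d <- random_dna(20)
    got <- scan_ese(u, d, toyset)
    want <- oracle_scan_ese(u, d, toyset)
    expect_equal(got$offset, want$offset)
    expect_equal(got$hexamer, want$hexamer)
  }
})

test_that("find_insertion_sites ranks a planted CAAG|G junction first", {
  set.seed(33)
  cds <- paste0(strrep("TC", 50), "CAAG", "G", strrep("CT", 50))
  sites <- find_insertion_sites(cds, hexamers = "GAAGAA")
  expect_equal(sites$cds_position[1], 104L)
  expect_equal(sites$consensus_score[1], 1)
  expect_equal(nrow(find_insertion_sites(strrep("C", 200))), 0L)
})

test_that("insertion-site composite decreases with first-exon length, all else equal", {
  # identical junction motif early and late in a long CDS
  block <- paste0(strrep("TC", 20), "CAAGG", strrep("CT", 20))
  cds <- paste0(block, strrep("TC", 1180), block)
  sites <- find_insertion_sites(cds)
  planted <- sites[sites$consensus_score == 1, ]
  expect_equal(nrow(planted), 2L)
  expect_equal(planted$cds_position[1], 44L) # the 100-nt-scale junction wins
  expect_gt(planted$composite[1], planted$composite[2])
  # recompute the composite by hand for the two sites
  w <- c(consensus = 0.5, ese = 0.2, first_exon = 0.2, dist3 = 0.1)
  manual <- w[["consensus"]] * planted$consensus_score +
    w[["ese"]] * pmin(planted$n_ese, 4) / 4 +
    w[["first_exon"]] * exp(-pmax(0, planted$first_exon_len - 374) / 430) +
    w[["dist3"]] * exp(-planted$dist_to_polya / 2000)
  expect_equal(planted$composite, manual)
  # monotonicity of the penalty itself
  fe <- sites$first_exon_score[order(sites$first_exon_len)]
  expect_true(all(diff(fe) <= 1e-12))
})

test_that("predict_splice_products enumerates k*m + 1 products with conserved lengths", {
  # cryptic donor 69 nt upstream of the intended donor, shared acceptor
  prod <- predict_splice_products(500, donors = c(100, 169), acceptors = 300,
                                  intended = c(169, 300))
  intended <- prod$product_length[prod$classification == "intended"]
  cryptic <- prod$product_length[prod$classification == "cryptic"]
  expect_equal(intended - cryptic, 69L)
  # single pair: intended + unspliced only
  p1 <- predict_splice_products(200, donors = 50, acceptors = 120)
  expect_setequal(p1$classification, c("intended", "unspliced"))
  # combinatorial count, donors all upstream of acceptors
  set.seed(34)
  for (i in 1:5) {
    k <- sample(1:4, 1); m <- sample(1:4, 1)
    d <- sort(sample(10:100, k)); a <- sort(sample(200:300, m))
    p <- predict_splice_products(400, d, a, intended = c(d[1], a[1]))
    expect_equal(nrow(p), k * m + 1L)
    spliced <- p[p$classification != "unspliced", ]
    expect_true(all(spliced$excised + spliced$product_length == 400))
  }
  expect_error(predict_splice_products(400, 300, 200), "intended")
})
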