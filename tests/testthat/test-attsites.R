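test_that("alignment trimming keeps the conserved terminal run", {
  rows <- rep("ACGTACGTAC", 4)
  out <- trim_alignment(rows, occupancy_min = 0.5, ic_min = 0)
  expect_identical(unname(unclass(out))[1:4], rows)
  ## last 20 columns 90% gaps -> removed at occupancy 0.5
  set.seed(1)
  core <- replicate(10, random_dna_for_test(30))
  tails <- vapply(1:10, function(i) {
    if (i == 1) random_dna_for_test(20) else strrep("-", 20)
  }, character(1))
  out2 <- trim_alignment(paste0(core, tails), occupancy_min = 0.5,
                         ic_min = 0, anchor = "left")
  expect_equal(unique(nchar(out2)), 30)
  expect_identical(attr(out2, "kept_columns"), 1:30)
  expect_warning(trim_alignment("ACGT"), "single-row")
  expect_error(trim_alignment(character(0)), class = "evetrace_input_error")
})

test_that("profile counts and log-odds match hand computation", {
  ## two sequences AC / AT, alpha = 0, uniform background
  p <- build_profile(c("AC", "AT"), side = "left", alpha = 0)
  expect_equal(unname(p$log_odds["A", 1]), log2(1 / 0.25))
  expect_equal(unname(p$log_odds["C", 2]), log2(0.5 / 0.25))
  expect_equal(unname(p$log_odds["T", 2]), log2(0.5 / 0.25))
  ## one sequence: consensus equals that sequence
  p1 <- build_profile("ACGTAC", side = "right", alpha = 1)
  expect_identical(p1$consensus, "ACGTAC")
  ## uniform column: all log-odds zero
  pu <- build_profile(c("A", "C", "G", "T"), side = "left", alpha = 0)
  expect_true(all(abs(pu$log_odds) < 1e-12))
  expect_error(build_profile(c("AC", "ACT")), class = "evetrace_input_error")
})

test_that("genome scanning equals exhaustive window scoring", {
  set.seed(21)
  motif <- random_dna_for_test(30)
  seqs <- replicate(15, {
    v <- strsplit(motif, "")[[1]]
    mut <- runif(30) < 0.1
    v[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(v, collapse = "")
  })
  prof <- build_profile(seqs, side = "left")
  contig <- paste0(random_dna_for_test(1400), motif, random_dna_for_test(1600))
  hits <- scan_genome(prof, c(chrZ = contig), allow_partial = FALSE,
                      background = "profile")
  ## top hit at the planted coordinate with the maximal window score
  sc_f <- oracle_window_scores(prof$log_odds, contig)
  sc_r <- oracle_window_scores(prof$log_odds, revcomp(contig))
  top <- hits[which.max(hits$score), ]
  expect_equal(top$start, 1400)
  expect_equal(top$score, max(sc_f, sc_r))
  expect_equal(top$score, sc_f[1401])
  ## every reported hit's score equals the oracle's at that window
  for (i in seq_len(nrow(hits))) {
    sc <- if (hits$strand[i] == "+") sc_f[hits$start[i] + 1] else
      sc_r[nchar(contig) - hits$end[i] + 1]
    expect_equal(hits$score[i], sc)
  }
  ## every oracle window above threshold overlaps a reported hit at least
  ## as good (greedy non-overlap selection)
  smin <- 0.6 * sum(apply(prof$log_odds, 2, max))
  for (st in which(sc_f >= smin) - 1) {
    ov <- hits$start < st + 30 & hits$end > st & hits$strand == "+"
    expect_true(any(ov) && max(hits$score[ov]) >= sc_f[st + 1] - 1e-9)
  }
})

test_that("scanning the reverse complement finds the same hit on '-'", {
  set.seed(22)
  motif <- random_dna_for_test(25)
  prof <- build_profile(rep(motif, 3), side = "left")
  contig <- paste0(random_dna_for_test(900), motif, random_dna_for_test(1000))
  h_f <- scan_genome(prof, c(c1 = contig), allow_partial = FALSE,
                     background = "profile")
  h_r <- scan_genome(prof, c(c1 = revcomp(contig)), allow_partial = FALSE,
                     background = "profile")
  top_f <- h_f[which.max(h_f$score), ]
  top_r <- h_r[which.max(h_r$score), ]
  expect_equal(top_f$score, top_r$score)
  expect_identical(top_f$strand, "+")
  expect_identical(top_r$strand, "-")
  expect_equal(top_r$start, nchar(contig) - top_f$end)
})

test_that("random contigs yield no hits at a stringent threshold", {
  set.seed(23)
  motif <- random_dna_for_test(40)
  prof <- build_profile(rep(motif, 5), side = "left")
  smax <- sum(apply(prof$log_odds, 2, max))
  for (s in 1:3) {
    contig <- random_dna_for_test(8000)
    hits <- scan_genome(prof, c(x = contig), score_min = 0.8 * smax,
                        allow_partial = FALSE, background = "profile")
    expect_equal(nrow(hits), 0)
  }
})

test_that("hit filtering applies inclusive 80 bp / 50 bp bounds", {
  hits <- data.frame(contig = "c", start = c(0, 100, 300, 500, 700),
                     end = c(79, 220, 380, 590, 790),
                     strand = "+", score = 10,
                     hit_len = c(79, 120, 80, 90, 80),
                     dist_to_model_end = c(0, 51, 50, 0, 51),
                     stringsAsFactors = FALSE)
  class(hits) <- c("terminus_hits", "data.frame")
  kept <- filter_hits(hits, min_len = 80, max_dist = 50)
  ## 79 bp removed; dist 51 removed; (80, 50) retained (inclusive)
  expect_equal(kept$hit_len, c(80, 90))
  expect_equal(kept$dist_to_model_end, c(50, 0))
  ## idempotent and order-preserving
  expect_equal(as.data.frame(filter_hits(kept)), as.data.frame(kept))
})

test_that("identical flanks collapse to a single terminus copy", {
  set.seed(24)
  flank <- random_dna_for_test(150)
  term <- random_dna_for_test(100)
  contigs <- c(cA = paste0(flank, term, random_dna_for_test(80)),
               cB = paste0(flank, term, random_dna_for_test(80)),
               cC = paste0(random_dna_for_test(150), term,
                           random_dna_for_test(80)))
  hits <- data.frame(contig = c("cA", "cB", "cC"), start = 150, end = 250,
                     strand = "+", score = 50, hit_len = 100,
                     dist_to_model_end = 0, stringsAsFactors = FALSE)
  class(hits) <- c("terminus_hits", "data.frame")
  attr(hits, "side") <- "left"
  dd <- dedup_flanks(hits, contigs, flank_w = 100)
  ## identical upstream flanks (cA, cB) collapse; different flank kept
  expect_equal(nrow(dd), 2)
  expect_setequal(dd$contig, c("cA", "cC"))
  dd2 <- dedup_flanks(dd, contigs, flank_w = 100)
  expect_equal(as.data.frame(dd2), as.data.frame(dd))
  ## flanks shorter than flank_w are compared as truncated strings
  hits_edge <- hits[1:2, ]
  class(hits_edge) <- class(hits); attr(hits_edge, "side") <- "left"
  dd3 <- dedup_flanks(hits_edge, contigs, flank_w = 500)
  expect_equal(nrow(dd3), 1)
})

test_that("logo information content matches its definition and bounds", {
  lg <- make_logo(c("CA", "CT"))
  expect_equal(lg$ic[1], 2)        # invariant column
  expect_equal(lg$ic[2], 1)        # {A: 0.5, T: 0.5} column
  lg0 <- make_logo(c("A", "C", "G", "T"))
  expect_equal(lg0$ic[1], 0)       # equifrequent column
  expect_true(all(abs(colSums(lg$freq) - 1) < 1e-12))
  ## property: IC within [0, 2] for random inputs
  set.seed(25)
  for (i in 1:20) {
    seqs <- replicate(sample(2:8, 1), random_dna_for_test(12))
    ic <- make_logo(seqs)$ic
    expect_true(all(ic >= 0 - 1e-12 & ic <= 2 + 1e-12))
  }
})

test_that("attB/attP consensus recovers the planted CC core from noisy sets", {
  set.seed(26)
  w <- 20
  attLs <- character(0); attRs <- character(0)
  for (i in 1:120) {
    mut <- function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- runif(length(v)) < 0.10
      v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(v, collapse = "")
    }
    attLs <- c(attLs, paste0(mut(random_dna_for_test(w - 5)), "ATA", "CC",
                             mut(random_dna_for_test(w))))
    attRs <- c(attRs, paste0(mut(random_dna_for_test(w - 2)), "CC",
                             mut(random_dna_for_test(w))))
  }
  cons <- infer_att_consensus(attLs, attRs, junction_L = w, junction_R = w)
  expect_true(grepl("CC$", cons$core))
  ## final two pre-junction columns are C,C with IC >= 1.5 bits each
  icL <- make_logo(substr(attLs, w - 1, w))$ic
  icR <- make_logo(substr(attRs, w - 1, w))$ic
  expect_true(all(icL >= 1.5))
  expect_true(all(icR >= 1.5))
  ## attB/attP rebuilt around the core
  expect_identical(substr(cons$attB, w - 1, w), "CC")
  expect_identical(substr(cons$attP, w - 1, w), "CC")
})

test_that("randomized flanks with a fixed CC junction give core exactly CC", {
  set.seed(27)
  w <- 15
  attLs <- vapply(1:50, function(i)
    paste0(random_dna_for_test(w - 2), "CC", random_dna_for_test(w)),
    character(1))
  attRs <- vapply(1:50, function(i)
    paste0(random_dna_for_test(w - 2), "CC", random_dna_for_test(w)),
    character(1))
  cons <- infer_att_consensus(attLs, attRs, junction_L = w, junction_R = w)
  expect_identical(cons$core, "CC")
})

test_that("single-pair consensus agrees with the extracted quartet", {
  fx <- toy_fixture(seed = 18)
  rec <- toy_junction(fx)
  w <- 30
  qt <- extract_att_quartet(rec, fx$integ$seq, fx$host, flank_w = w)
  cons <- infer_att_consensus(qt$attL, qt$attR,
                              junction_L = w + rec$core_len,
                              junction_R = w + rec$core_len)
  expect_identical(cons$attB, qt$attB)
  expect_identical(cons$attP, qt$attP)
  expect_identical(cons$core, qt$core)
})

test_that("repeat finding matches the textbook examples", {
  pal <- find_inverted_repeats("GAATTC", min_arm = 3, max_loop = 0)
  expect_equal(nrow(pal), 1)
  expect_equal(pal$arm_len, 3)
  expect_equal(pal$loop_len, 0)
  expect_equal(pal$mismatches, 0)

  ir <- find_inverted_repeats("AAAATTTT", min_arm = 4, max_loop = 0)
  best <- ir[which.max(ir$arm_len), ]
  expect_equal(best$arm_len, 4)
  expect_equal(best$at_fraction, 1.0)

  dr <- find_inverted_repeats("ACGTACGT", min_arm = 4, max_loop = 0,
                              kind = "direct")
  best_dr <- dr[which.max(dr$arm_len), ]
  expect_equal(best_dr$arm_len, 4)
  expect_equal(best_dr$left_start, 0)
  expect_equal(best_dr$right_start, 4)

  ## the planted telRL outer inverted repeat is recovered from the EVE
  eve <- make_eve(eve_spec(length_bp = 3000, seed = 29))
  tr <- eve$truth
  tb <- tr[tr$feature == "telRL_outer_ir", ]
  region <- substr(eve$seq[[1]], tb$start - 4, tb$end + 5)
  hits <- find_inverted_repeats(region, min_arm = 10, max_loop = 14)
  expect_true(any(hits$arm_len >= 15 & hits$loop_len == 12))
})
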