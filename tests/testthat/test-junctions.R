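test_that("anchor mapping handles identity, reverse complement and insertions", {
  set.seed(101)
  s <- random_dna_for_test(1000)
  am <- anchor_map(c(a = s), c(b = s))
  expect_equal(nrow(am$chain), 1)
  expect_equal(am$chain$length, 1000)
  expect_equal(am$chain$query_start, 0)
  expect_equal(am$chain_strand, "+")

  am_rc <- anchor_map(c(a = revcomp(s)), c(b = s))
  expect_equal(am_rc$chain_strand, "-")
  expect_equal(nrow(am_rc$chain), 1)
  expect_equal(am_rc$chain$length, 1000)

  ## 200-bp insertion in the reference relative to the query
  ins <- random_dna_for_test(200)
  r2 <- paste0(substr(s, 1, 600), ins, substr(s, 601, 1000))
  am2 <- anchor_map(c(a = s), c(b = r2))
  ch <- am2$chain
  expect_gte(nrow(ch), 2)
  qgap <- ch$query_start[nrow(ch)] - (ch$query_start[1] + ch$length[1])
  rgap <- ch$ref_start[nrow(ch)] - (ch$ref_start[1] + ch$length[1])
  expect_lte(abs(qgap), 5)
  expect_lte(abs(rgap - 200), 5)
  expect_error(anchor_map(c(a = s), c(b = s), k = 9),
               class = "evetrace_input_error")
})

test_that("anchor enumeration equals the brute-force maximal-exact-match oracle", {
  set.seed(77)
  for (i in 1:5) {
    q <- random_dna_for_test(400)
    shared1 <- substr(q, 51, 130)
    shared2 <- substr(q, 201, 260)
    r <- paste0(random_dna_for_test(40), shared1, random_dna_for_test(60),
                revcomp(shared2), random_dna_for_test(40))
    got <- anchor_map(c(q = q), c(r = r), k = 15)$anchors
    got <- got[order(got$strand, got$query_start, got$ref_start), ]
    want <- oracle_mems(q, r, 15)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[c("query_start", "ref_start", "length", "strand")],
                 want[c("query_start", "ref_start", "length", "strand")])
  }
  ## and on a full simulated bearing/free pair (<= 2 kb)
  fx <- toy_fixture(seed = 31, host_len = 1200, eve_len = 700,
                    site_frac = 0.5)
  got <- anchor_map(fx$integ$seq, fx$host, k = 15)$anchors
  got <- got[order(got$strand, got$query_start, got$ref_start), ]
  want <- oracle_mems(fx$integ$seq[[1]], fx$host[[1]], 15)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[c("query_start", "ref_start", "length", "strand")],
               want[c("query_start", "ref_start", "length", "strand")])
})

test_that("insertions resolve exactly against the EVE-free homolog", {
  for (seed in c(1, 2, 3, 4, 5)) {
    fx <- toy_fixture(seed = seed, host_len = 4000 + 300 * seed,
                      eve_len = 2500 + 200 * seed,
                      site_frac = 0.3 + 0.05 * seed)
    rec <- resolve_insertion(fx$integ$seq, fx$host)
    expect_equal(nrow(rec), 1)
    expect_equal(rec$insert_start, fx$truth_interval[1])
    expect_equal(rec$insert_end, fx$truth_interval[2])
    expect_equal(rec$ambiguity_shift, 2L)
  }
})

test_that("identical haplotypes resolve to no insertion, not an error", {
  g <- make_host_genome(1, 3000, 0.5, seed = 44)
  rec <- resolve_insertion(g[1], g[1])
  expect_s3_class(rec, "junction_record")
  expect_equal(nrow(rec), 0)
})

test_that("two insertions on one chromosome give disjoint records", {
  host <- make_host_genome(1, 8000, 0.5, seed = 17)
  s1 <- 2500L; s2 <- 6000L
  h <- plant_attB(plant_attB(host[[1]], s1), s2)
  eve1 <- make_eve(eve_spec(length_bp = 1500, seed = 61), id = "EVEh")
  eve2 <- make_eve(eve_spec(length_bp = 1800, seed = 62), id = "EVEi")
  ## insert right-to-left so the first site's coordinates are unaffected
  b <- integrate_eve(c(chr23 = h), eve2$seq, s2, "CC")$seq
  b <- integrate_eve(b, eve1$seq, s1, "CC")$seq
  recs <- resolve_insertion(setNames(b[1], "chr23_bearing"), c(chr23 = h))
  expect_equal(nrow(recs), 2)
  recs <- recs[order(recs$insert_start), ]
  expect_lte(recs$insert_end[1], recs$insert_start[2])
  expect_equal(recs$insert_end[1] - recs$insert_start[1], 1500)
  expect_equal(recs$insert_end[2] - recs$insert_start[2], 1800)
})

test_that("recombinase-core junctions classify with a 2-bp CC core", {
  fx <- toy_fixture(seed = 8)
  rec <- toy_junction(fx)
  expect_identical(rec$mechanism, "recombinase_core")
  expect_identical(rec$core, "CC")
  expect_equal(rec$core_len, 2)
  expect_equal(rec$tsd_len, 0)
  expect_true(is.na(rec$tsd))
  expect_gte(rec$ambiguity_shift, rec$core_len)
})

test_that("a GC-core junction variant classifies identically", {
  set.seed(55)
  host_seq <- random_dna_for_test(3000)
  site <- 1500L
  host_seq <- paste0(substr(host_seq, 1, site - 5), "ATAGC", "A",
                     substr(host_seq, site + 2, 3000))
  eve <- make_eve(eve_spec(length_bp = 1500, attP_core = "GC", seed = 56))
  integ <- integrate_eve(c(chrF = host_seq), eve$seq, site, "GC",
                         eve_truth = eve$truth)
  rec <- resolve_insertion(integ$seq, c(chrF = host_seq))
  es <- eve$seq[[1]]
  rec <- classify_mechanism(rec[1, ], integ$seq, c(chrF = host_seq),
                            substr(es, 1, 200),
                            substr(es, nchar(es) - 199, nchar(es)))
  expect_identical(rec$mechanism, "recombinase_core")
  expect_identical(rec$core, "GC")
})

test_that("IS4-style insertions classify as an 8-nt target site duplication", {
  eve_free <- make_eve(eve_spec(length_bp = 5000, seed = 13))
  eve_tn <- make_eve(eve_spec(length_bp = 5000,
                              transposon = is4_spec(length_bp = 800),
                              seed = 13))
  rec <- resolve_insertion(eve_tn$seq, eve_free$seq)
  rec <- classify_mechanism(rec[1, ], eve_tn$seq, eve_free$seq)
  expect_identical(rec$mechanism, "dde_tsd")
  expect_equal(rec$tsd_len, 8)
  expect_equal(nchar(rec$tsd), 8)
  expect_equal(rec$core_len, 0)
  ## the duplication matches the truth target site
  tsd_truth <- eve_tn$truth[eve_tn$truth$feature == "TSD", ]
  expect_identical(rec$tsd, sub("^left;", "", tsd_truth$detail[1]))
})

test_that("blunt insertions stay unclassified and the mechanisms are exclusive", {
  set.seed(66)
  host_seq <- random_dna_for_test(2000)
  site <- 1000L
  ins <- random_dna_for_test(300)
  ## force non-matching terminal bases so no microhomology arises
  h_after <- substr(host_seq, site + 1, site + 1)
  h_before <- substr(host_seq, site, site)
  ins <- paste0(setdiff(c("A", "C", "G", "T"), h_after)[1],
                substr(ins, 2, 299),
                setdiff(c("A", "C", "G", "T"), h_before)[1])
  bearing <- paste0(substr(host_seq, 1, site), ins,
                    substr(host_seq, site + 1, 2000))
  rec <- resolve_insertion(c(b = bearing), c(f = host_seq))
  rec <- classify_mechanism(rec[1, ], c(b = bearing), c(f = host_seq),
                            substr(ins, 1, 50), substr(ins, 251, 300))
  expect_identical(rec$mechanism, "unclassified")
  expect_equal(rec$core_len, 0)
  expect_equal(rec$ambiguity_shift, 0)
  ## exhaustiveness over the three mechanisms
  fx <- toy_fixture(seed = 9)
  expect_true(toy_junction(fx)$mechanism %in%
                c("recombinase_core", "dde_tsd", "unclassified"))
})

test_that("sliding the breakpoint within the microhomology is sequence-neutral", {
  fx <- toy_fixture(seed = 12)
  rec <- toy_junction(fx)
  b <- fx$integ$seq[[1]]
  reconstruct <- function(is0, ie0) {
    paste0(substr(b, 1, is0), substr(b, ie0 + 1, nchar(b)))
  }
  base <- reconstruct(rec$insert_start, rec$insert_end)
  for (d in seq_len(rec$ambiguity_shift)) {
    expect_identical(reconstruct(rec$insert_start + d, rec$insert_end + d),
                     base)
  }
  expect_identical(base, fx$host[[1]])
})

test_that("the attachment-site quartet matches its defining constructions", {
  fx <- toy_fixture(seed = 14)
  rec <- toy_junction(fx)
  w <- 25
  qt <- extract_att_quartet(rec, fx$integ$seq, fx$host, flank_w = w)
  cl <- rec$core_len
  ## attL prefix matches attB prefix; attR suffix matches attB suffix
  expect_identical(substr(qt$attL, 1, w + cl), substr(qt$attB, 1, w + cl))
  expect_identical(substr(qt$attR, w + 1, 2 * w + cl),
                   substr(qt$attB, w + 1, 2 * w + cl))
  ## core is a substring of all four sites
  for (site in c(qt$attB, qt$attP, qt$attL, qt$attR))
    expect_true(grepl(qt$core, site, fixed = TRUE))
  ## attP equals the junction sequence of the excised circle
  exc <- excise_to_circle(fx$integ$seq, fx$integ$truth)
  circ <- exc$circle[[1]]
  circ_junction <- paste0(substr(circ, nchar(circ) - w + 1, nchar(circ)),
                          substr(circ, 1, w + cl))
  expect_identical(qt$attP, circ_junction)
  ## attL/attR assemble from host flank + core + viral terminus
  es <- fx$eve$seq[[1]]
  host_left <- substr(fx$host[[1]], fx$site - cl - w + 1, fx$site)
  expect_identical(qt$attL, paste0(host_left, substr(es, 1, w)))
  ## contract error on non-recombinase junctions
  rec_bad <- rec; rec_bad$mechanism <- "unclassified"
  expect_error(extract_att_quartet(rec_bad, fx$integ$seq, fx$host),
               class = "evetrace_contract_error")
})

test_that("resolution is exact over random fixtures and robust to 2% noise", {
  exact <- 0; close2 <- 0; n_exact <- 20; n_noisy <- 20
  for (i in seq_len(n_exact)) {
    fx <- toy_fixture(seed = 200 + i,
                      host_len = 3000 + 200 * (i %% 7),
                      eve_len = 1500 + 300 * (i %% 5),
                      site_frac = 0.25 + 0.02 * i)
    rec <- resolve_insertion(fx$integ$seq, fx$host)
    if (nrow(rec) == 1 && rec$insert_start == fx$truth_interval[1] &&
        rec$insert_end == fx$truth_interval[2]) exact <- exact + 1
  }
  expect_equal(exact, n_exact)
  set.seed(303)
  for (i in seq_len(n_noisy)) {
    fx <- toy_fixture(seed = 400 + i)
    noisy <- evetrace:::mutate_seq(fx$integ$seq[[1]], 0.02)
    rec <- tryCatch(resolve_insertion(c(noisy = noisy), fx$host),
                    error = function(e) NULL)
    if (!is.null(rec) && nrow(rec) >= 1) {
      d <- max(abs(rec$insert_start - fx$truth_interval[1]),
               abs(rec$insert_end - fx$truth_interval[2]))
      if (min(d) <= 2) close2 <- close2 + 1
    }
  }
  expect_gte(close2 / n_noisy, 0.8)
})
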