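## Independent brute-force oracles and small fixture builders.

## Enumerate all maximal exact matches >= k between two strings on the
## forward strand by scanning every diagonal with vectorized comparison
## and run-length encoding — independent of the k-mer/merge implementation.
oracle_mems_forward <- function(q, r, k) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  rv <- strsplit(r, "", fixed = TRUE)[[1]]
  nq <- length(qv); nr <- length(rv)
  out <- list()
  for (d in (-(nq - 1)):(nr - 1)) {
    qi <- max(1, 1 - d):min(nq, nr - d)
    if (length(qi) < k) next
    eq <- qv[qi] == rv[qi + d]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (j in which(rl$values & rl$lengths >= k)) {
      out[[length(out) + 1]] <- data.frame(
        query_start = qi[starts[j]] - 1L,
        ref_start = qi[starts[j]] - 1L + d,
        length = rl$lengths[j])
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_start = integer(), ref_start = integer(),
                      length = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$query_start, res$ref_start), , drop = FALSE]
}

oracle_mems <- function(q, r, k) {
  fwd <- oracle_mems_forward(q, r, k)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- oracle_mems_forward(q, revcomp(r), k)
  if (nrow(rc) > 0) {
    rc$ref_start <- nchar(r) - rc$ref_start - rc$length
    rc$strand <- "-"
  } else rc$strand <- character(0)
  res <- rbind(fwd, rc)
  res[order(res$strand, res$query_start, res$ref_start), , drop = FALSE]
}

## Exhaustive window scoring of a profile over one strand of a contig.
oracle_window_scores <- function(log_odds, contig) {
  v <- strsplit(contig, "", fixed = TRUE)[[1]]
  codes <- match(v, c("A", "C", "G", "T"))
  L <- ncol(log_odds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  vapply(0:(n - L), function(st) {
    sum(log_odds[cbind(codes[(st + 1):(st + L)], 1:L)])
  }, numeric(1))
}

## Plain random DNA for toy constructions (independent of the package's
## generator internals).
random_dna_for_test <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Small integrated-EVE fixture used across modules.
toy_fixture <- function(seed = 1, host_len = 4000L, eve_len = 2500L,
                        site_frac = 0.5, transposon = NULL) {
  host <- make_host_genome(1, host_len, 0.5, seed = seed)
  site <- as.integer(host_len * site_frac)
  host[1] <- plant_attB(host[[1]], site)
  es <- eve_spec(length_bp = eve_len, transposon = transposon,
                 seed = seed + 1000L)
  eve <- make_eve(es)
  integ <- integrate_eve(host[1], eve$seq, site, es$attP_core,
                         eve_truth = eve$truth)
  list(host = host[1], eve = eve, spec = es, integ = integ, site = site,
       truth_interval = {
         ei <- integ$truth[integ$truth$feature == "EVE_interval", ]
         c(ei$start[1], ei$end[1])
       })
}

## Classified junction record for a fixture.
toy_junction <- function(fx) {
  rec <- resolve_insertion(fx$integ$seq, fx$host)
  eseq <- fx$eve$seq[[1]]
  classify_mechanism(rec[1, ], fx$integ$seq, fx$host,
                     eve_left_end = substr(eseq, 1, 200),
                     eve_right_end = substr(eseq, nchar(eseq) - 199,
                                            nchar(eseq)))
}

## Symptomatic or asymptomatic read set over a fixture.
toy_reads <- function(fx, symptomatic = TRUE, seed = 1,
                      depths = c(integrated = 4, circle = 10, hairpin = 10,
                                 host_background = 4),
                      read_length = c(500, 80)) {
  exc <- excise_to_circle(fx$integ$seq, fx$integ$truth)
  hp <- make_hairpin_templates(exc$circle, fx$spec$telrl, arm_len = 800L)
  if (!symptomatic) depths <- depths[c("integrated", "host_background")]
  rspec <- read_sim_spec(depths, read_length = read_length, error_rate = 0,
                         seed = seed)
  reads <- simulate_reads(list(integrated = fx$integ$seq,
                               circle = exc$circle, hairpin = hp,
                               host_background = exc$restored_host), rspec)
  list(reads = reads, circle = exc$circle, hairpins = hp,
       restored = exc$restored_host,
       apex_center_circle = attr(hp, "apex_center"))
}
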