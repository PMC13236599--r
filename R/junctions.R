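## Exact insertion-junction resolution: anchor mapping between the
## EVE-bearing haplotype and its EVE-free homolog, microhomology
## quantification, mechanism classification and attachment-site
## extraction.

## Keyed k-mer table of a reference string, shared across many queries.
ref_kmer_table <- function(reference, k) {
  nr <- nchar(reference)
  if (nr < k) {
    rdt <- data.table::data.table(kmer = character(), rpos = integer())
  } else {
    rpos <- 0:(nr - k)
    rdt <- data.table::data.table(kmer = substring(reference, rpos + 1L,
                                                   rpos + k),
                                  rpos = rpos)
  }
  data.table::setkey(rdt, kmer)
  rdt
}

## Index of a reference (both strands) for repeated anchor mapping.
ref_index <- function(reference, k) {
  rseq <- unname(reference[1])
  list(seq = rseq, nr = nchar(rseq), k = as.integer(k),
       id = names(reference)[1] %||% "ref",
       fwd = ref_kmer_table(rseq, k),
       rev = ref_kmer_table(revcomp(rseq), k))
}

## Enumerate maximal exact matches (>= k) between two plain strings on the
## forward strand, as (query_start, ref_start, length), 0-based. k-mer hits
## are collapsed along diagonals; a run of consecutive hits on one diagonal
## is exactly one maximal match.
mem_forward <- function(query, rdt, k) {
  nq <- nchar(query)
  if (nq < k || nrow(rdt) == 0) {
    return(data.frame(query_start = integer(), ref_start = integer(),
                      length = integer()))
  }
  qpos <- 0:(nq - k)
  qk <- substring(query, qpos + 1L, qpos + k)
  qdt <- data.table::data.table(kmer = qk, qpos = qpos)
  hits <- rdt[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(data.frame(query_start = integer(), ref_start = integer(),
                      length = integer()))
  }
  hits[, diag := rpos - qpos]
  data.table::setorder(hits, diag, qpos)
  hits[, run := cumsum(c(1L, (diff(qpos) != 1L) | (diff(diag) != 0L)))]
  runs <- hits[, .(query_start = qpos[1], ref_start = rpos[1],
                   length = qpos[.N] - qpos[1] + k), by = run]
  as.data.frame(runs[, .(query_start, ref_start, length)])
}

#' Map a query onto a reference by maximal exact matches and chaining
#'
#' Enumerates all maximal exact matches of length at least `k` on both
#' strands and selects the highest-scoring colinear chain per strand
#' (score = summed anchor length; small overlaps between adjacent
#' anchors, as arise from junction microhomology, are permitted).
#'
#' @param query,reference DNA strings (named vectors accepted; first
#'   element used).
#' @param k minimum exact-match length (default 15, must be >= 11).
#' @return an object of class `anchor_chain`: list with `anchors` (all
#'   maximal exact matches, columns `query_start`, `ref_start`, `length`,
#'   `strand`), `chain` (the best colinear chain), `chain_strand`,
#'   `score`, `query_id`, `ref_id`, `k`. Coordinates are 0-based
#'   half-open; for `-` strand anchors `query[qs..qs+len)` equals the
#'   reverse complement of `reference[rs..rs+len)`.
#' @export
anchor_map <- function(query, reference, k = 15L) {
  k <- as.integer(k)
  if (k < 11) stop_input("k must be >= 11")
  qseq <- unname(query[1])
  if (!nzchar(qseq) || !nzchar(unname(reference[1])))
    stop_input("sequences must be non-empty")
  idx <- if (is.list(reference) && !is.null(reference$fwd)) reference
         else ref_index(reference, k)
  anchor_map_idx(qseq, idx, qid = names(query)[1] %||% "query")
}

anchor_map_idx <- function(qseq, idx, qid = "query") {
  k <- idx$k
  fwd <- mem_forward(qseq, idx$fwd, k)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- mem_forward(qseq, idx$rev, k)
  if (nrow(rev) > 0) {
    rev$ref_start <- idx$nr - rev$ref_start - rev$length
    rev$strand <- "-"
  } else rev$strand <- character(0)
  anchors <- rbind(fwd, rev)

  chain_f <- chain_anchors(fwd, k)
  ## chain on '-' strand: colinear in query and in reverse-complement ref
  rev_rc <- rev
  if (nrow(rev_rc) > 0) {
    rev_rc$ref_start <- idx$nr - rev_rc$ref_start - rev_rc$length
  }
  chain_r <- chain_anchors(rev_rc, k)
  if (chain_r$score > 0 && nrow(chain_r$chain) > 0) {
    chain_r$chain$ref_start <- idx$nr - chain_r$chain$ref_start -
      chain_r$chain$length
  }
  if (chain_f$score >= chain_r$score) {
    chain <- chain_f$chain; strand <- "+"; score <- chain_f$score
  } else {
    chain <- chain_r$chain; strand <- "-"; score <- chain_r$score
  }
  if (nrow(chain) > 0) chain$strand <- strand
  structure(list(anchors = anchors, chain = chain, chain_strand = strand,
                 score = score, query_id = qid, ref_id = idx$id, k = k),
            class = "anchor_chain")
}

## Anchor every read against a shared reference index; returns a list of
## anchor data frames (all maximal exact matches, both strands).
read_anchors <- function(reads, ref, k = 15L) {
  idx <- ref_index(ref, k)
  lapply(seq_along(reads), function(i)
    anchor_map_idx(unname(reads[i]), idx)$anchors)
}

## Best colinear chain recomputed from a precomputed anchor table.
best_chain_from_anchors <- function(anchors, nr, k) {
  fwd <- anchors[anchors$strand == "+", , drop = FALSE]
  rev_rc <- anchors[anchors$strand == "-", , drop = FALSE]
  if (nrow(rev_rc) > 0) {
    rev_rc$ref_start <- nr - rev_rc$ref_start - rev_rc$length
  }
  cf <- chain_anchors(fwd, k)
  cr <- chain_anchors(rev_rc, k)
  if (cf$score >= cr$score) return(cf$chain)
  ch <- cr$chain
  if (nrow(ch) > 0) ch$ref_start <- nr - ch$ref_start - ch$length
  ch
}

## Best colinear chain by dynamic programming over anchors sorted by query
## start. Adjacent anchors may overlap by up to k-1 bp in either
## coordinate (junction microhomology); larger overlaps break colinearity.
chain_anchors <- function(anchors, k) {
  n <- nrow(anchors)
  if (n == 0) return(list(chain = anchors, score = 0))
  ord <- order(anchors$query_start, anchors$ref_start)
  a <- anchors[ord, , drop = FALSE]
  maxov <- k - 1L
  score <- a$length
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    qs <- a$query_start[i]; rs <- a$ref_start[i]
    for (j in seq_len(i - 1)) {
      if (a$query_start[j] < qs && a$ref_start[j] < rs &&
          a$query_start[j] + a$length[j] <= qs + maxov &&
          a$ref_start[j] + a$length[j] <= rs + maxov) {
        cand <- score[j] + a$length[i]
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  best <- which.max(score)
  idx <- best
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  list(chain = a[idx, c("query_start", "ref_start", "length"),
                 drop = FALSE],
       score = score[best])
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat(sprintf("anchor_chain: %s vs %s (k=%d)\n", x$query_id, x$ref_id, x$k))
  cat(sprintf("  %d maximal exact matches; best chain: %d anchors, score %d (%s strand)\n",
              nrow(x$anchors), nrow(x$chain), x$score, x$chain_strand))
  invisible(x)
}

new_junction_record <- function(chrom, insert_start, insert_end, homology,
                                ambiguity_shift) {
  structure(data.frame(chrom = chrom,
                       insert_start = as.integer(insert_start),
                       insert_end = as.integer(insert_end),
                       homology = homology,
                       ambiguity_shift = as.integer(ambiguity_shift),
                       core = NA_character_, core_len = 0L,
                       tsd = NA_character_, tsd_len = 0L,
                       mechanism = "unclassified",
                       stringsAsFactors = FALSE),
            class = c("junction_record", "data.frame"))
}

#' Resolve EVE insertion coordinates against the EVE-free homolog
#'
#' Chains maximal exact matches between the EVE-bearing haplotype and the
#' homologous EVE-free sequence and reports each chain gap that is long
#' in the bearing haplotype but (near) absent in the homolog as an
#' insertion. When the flanking matches overlap on the homolog, the
#' breakpoint is ambiguous over that microhomology and the insert
#' interval is reported leftmost-canonical on the forward strand.
#'
#' @param bearing named DNA string carrying the insertion(s).
#' @param free named DNA string of the EVE-free homolog.
#' @param k anchor seed length (default 15).
#' @param min_insert smallest query gap reported as an insertion
#'   (default 50 bp).
#' @param min_flank minimum flanking anchor support on each side
#'   (default 30 bp).
#' @param gap_tol largest anchor gap (both coordinates) bridged within a
#'   colinear flank block, and the largest homolog-side gap tolerated at
#'   an insertion (default 30 bp).
#' @return a `junction_record` data frame, one row per insertion (zero
#'   rows when the sequences are colinear). Columns: `chrom` (homolog
#'   id), `insert_start`/`insert_end` (0-based half-open on the bearing
#'   haplotype, leftmost-canonical), `homology` (the shared junction
#'   string), `ambiguity_shift`, and classification fields filled by
#'   [classify_mechanism()].
#' @export
resolve_insertion <- function(bearing, free, k = 15L, min_insert = 50L,
                              min_flank = 30L, gap_tol = 30L) {
  am <- anchor_map(bearing, free, k)
  chain <- am$chain
  recs <- NULL
  bseq <- unname(bearing[1])
  if (am$chain_strand == "+" && nrow(chain) >= 2) {
    ## merge chain anchors into colinear blocks: small gaps in both
    ## coordinates (substitution noise) do not break a block
    n <- nrow(chain)
    qgap <- chain$query_start[-1] - (chain$query_start[-n] + chain$length[-n])
    rgap <- chain$ref_start[-1] - (chain$ref_start[-n] + chain$length[-n])
    brk <- qgap > gap_tol | rgap > gap_tol
    block_id <- cumsum(c(1L, as.integer(brk)))
    blocks <- do.call(rbind, lapply(split(seq_len(n), block_id), function(ix) {
      data.frame(q_start = chain$query_start[ix[1]],
                 q_end = chain$query_start[ix[length(ix)]] +
                   chain$length[ix[length(ix)]],
                 r_start = chain$ref_start[ix[1]],
                 r_end = chain$ref_start[ix[length(ix)]] +
                   chain$length[ix[length(ix)]],
                 support = sum(chain$length[ix]))
    }))
    if (nrow(blocks) >= 2) {
      fseq <- unname(free[1])
      for (i in seq_len(nrow(blocks) - 1)) {
        p <- blocks[i, ]; q <- blocks[i + 1, ]
        if (p$support < min_flank || q$support < min_flank) next
        ## breakpoint refinement is needed only when the flank blocks are
        ## fragmented by substitution noise (a clean flank is one maximal
        ## exact match reaching the junction); refining clean flanks could
        ## only chase chance matches past the true junction
        pe <- c(p$q_end, p$r_end)
        if (p$support < p$q_end - p$q_start) {
          pe <- refine_breakpoint(bseq, fseq, p$q_end, p$r_end, +1L,
                                  limit = min(3L * k, q$q_start - p$q_end))
        }
        qs <- c(q$q_start, q$r_start)
        if (q$support < q$q_end - q$q_start) {
          qs <- refine_breakpoint(bseq, fseq, q$q_start, q$r_start, -1L,
                                  limit = min(3L * k, q$q_start - p$q_end))
        }
        bq <- qs[1] - pe[1]
        br <- qs[2] - pe[2]
        o <- max(0L, -br)
        if (bq + o < min_insert || br > gap_tol) next
        is0 <- pe[1] - o
        ie0 <- qs[1]
        rec <- new_junction_record(am$ref_id, is0, ie0,
                                   subseq0(bseq, is0, is0 + o), o)
        recs <- if (is.null(recs)) rec else rbind(recs, rec)
      }
    }
  }
  if (is.null(recs)) {
    recs <- data.frame(chrom = character(), insert_start = integer(),
                       insert_end = integer(), homology = character(),
                       ambiguity_shift = integer(), core = character(),
                       core_len = integer(), tsd = character(),
                       tsd_len = integer(), mechanism = character(),
                       stringsAsFactors = FALSE)
    class(recs) <- c("junction_record", "data.frame")
    if (nchar(bseq) - nchar(unname(free[1])) >= min_insert) {
      stop(errorCondition(
        "length difference suggests an insertion but no flanking anchors were found",
        class = c("evetrace_resolution_error", "error")))
    }
  }
  class(recs) <- c("junction_record", "data.frame")
  recs
}

## Extend a flank's breakpoint past anchor fragmentation caused by
## substitution noise. Walks base-by-base from (q0, r0) in `direction`
## (+1 forward for a left flank end, -1 backward for a right flank
## start), scoring each position with the log-likelihood ratio of
## "still inside the shared flank" (match p ~ 0.98) versus "past the
## junction" (match p = 0.25); the leftmost cumulative-score maximum is
## the refined breakpoint. Returns c(q, r).
refine_breakpoint <- function(bseq, fseq, q0, r0, direction,
                              limit, match_lo = 1.37, mismatch_lo = -3.6) {
  if (limit <= 0) return(c(q0, r0))
  jmax <- if (direction > 0) {
    min(limit, nchar(bseq) - q0, nchar(fseq) - r0)
  } else {
    min(limit, q0, r0)
  }
  if (jmax <= 0) return(c(q0, r0))
  j <- seq_len(jmax)
  if (direction > 0) {
    bq <- substring(bseq, q0 + j, q0 + j)
    fr <- substring(fseq, r0 + j, r0 + j)
  } else {
    bq <- substring(bseq, q0 - j + 1L, q0 - j + 1L)
    fr <- substring(fseq, r0 - j + 1L, r0 - j + 1L)
  }
  s <- cumsum(ifelse(bq == fr, match_lo, mismatch_lo))
  best <- which.max(c(0, s)) - 1L
  c(q0 + direction * best, r0 + direction * best)
}

## Rotate a string left by o characters.
rotate_left <- function(s, o) {
  n <- nchar(s)
  o <- o %% n
  if (o == 0) return(s)
  paste0(subseq0(s, o, n), subseq0(s, 0L, o))
}

#' Classify the integration mechanism at a resolved junction
#'
#' Distinguishes transposase insertions, which duplicate the target site
#' on both sides (a TSD of length >= `tsd_min`), from site-specific
#' recombinase integration across a short shared core, in which the
#' junction microhomology also terminates the viral attachment site: the
#' leftmost-canonical insert, rotated by the microhomology length, must
#' reconstruct the element in its integrated orientation (left terminus
#' first, core-bearing right terminus last). Junctions with no shared
#' sequence, or shared sequence matching neither model, stay
#' `unclassified`.
#'
#' @param rec a one-row `junction_record` from [resolve_insertion()].
#' @param bearing,free the haplotype pair used for resolution.
#' @param eve_left_end,eve_right_end terminal sequences of the candidate
#'   element in integrated orientation (the right end includes the
#'   element's core copy). Used only for the recombinase check; pass
#'   `NULL` to skip it.
#' @param tsd_min smallest duplication called as a TSD (default 4).
#' @param core_max longest shared string considered a recombinase core
#'   (default 10).
#' @return the updated `junction_record` with `mechanism`, `core`,
#'   `core_len`, `tsd`, `tsd_len` filled.
#' @export
classify_mechanism <- function(rec, bearing, free, eve_left_end = NULL,
                               eve_right_end = NULL, tsd_min = 4L,
                               core_max = 10L) {
  stopifnot(inherits(rec, "junction_record"), nrow(rec) == 1)
  o <- rec$ambiguity_shift
  s <- rec$homology
  bseq <- unname(bearing[1])
  if (o >= tsd_min) {
    rec$mechanism <- "dde_tsd"
    rec$tsd <- s
    rec$tsd_len <- o
    rec$core <- NA_character_
    rec$core_len <- 0L
    return(rec)
  }
  if (o >= 1 && o <= core_max && !is.null(eve_left_end) &&
      !is.null(eve_right_end)) {
    insert <- subseq0(bseq, rec$insert_start, rec$insert_end)
    rot <- rotate_left(insert, o)
    wl <- min(nchar(eve_left_end), nchar(rot))
    wr <- min(nchar(eve_right_end), nchar(rot))
    ok_left <- substr(rot, 1, wl) == substr(eve_left_end, 1, wl)
    ok_right <- substr(rot, nchar(rot) - wr + 1L, nchar(rot)) ==
      substr(eve_right_end, nchar(eve_right_end) - wr + 1L,
             nchar(eve_right_end))
    if (ok_left && ok_right) {
      rec$mechanism <- "recombinase_core"
      rec$core <- s
      rec$core_len <- o
      rec$tsd <- NA_character_
      rec$tsd_len <- 0L
      return(rec)
    }
  }
  rec$mechanism <- "unclassified"
  rec
}

#' Extract the attB/attP/attL/attR attachment-site quartet
#'
#' Cuts the four attachment sites implied by a recombinase-core junction:
#' attB from the EVE-free homolog centred on the core, attL/attR from
#' the bearing haplotype at the two junctions, and attP by joining the
#' element's right terminus to its left terminus across one core copy
#' (the junction of the excised circle).
#'
#' @param rec a classified one-row `junction_record` with mechanism
#'   `recombinase_core`.
#' @param bearing,free the haplotype pair.
#' @param flank_w flank width on each side of the core (default 30).
#' @return an object of class `att_quartet`: list with `attB`, `attP`,
#'   `attL`, `attR`, `core`, `flank_w`.
#' @export
extract_att_quartet <- function(rec, bearing, free, flank_w = 30L) {
  stopifnot(inherits(rec, "junction_record"), nrow(rec) == 1)
  if (!identical(rec$mechanism, "recombinase_core"))
    stop_contract("attachment sites are defined only for recombinase_core ",
                  "junctions (got '", rec$mechanism, "')")
  w <- as.integer(flank_w)
  cl <- rec$core_len
  is0 <- rec$insert_start; ie0 <- rec$insert_end
  bseq <- unname(bearing[1]); fseq <- unname(free[1])
  attB <- subseq0(fseq, is0 - w, is0 + cl + w)
  attL <- subseq0(bseq, is0 - w, is0 + cl + w)
  attR <- subseq0(bseq, ie0 - w, ie0 + cl + w)
  attP <- paste0(subseq0(bseq, ie0 - w, ie0 + cl),
                 subseq0(bseq, is0 + cl, is0 + cl + w))
  structure(list(attB = attB, attP = attP, attL = attL, attR = attR,
                 core = rec$core, flank_w = w),
            class = "att_quartet")
}

#' @export
print.att_quartet <- function(x, ...) {
  cat("attachment-site quartet (core '", x$core, "', flank ", x$flank_w,
      " bp)\n", sep = "")
  for (nm in c("attB", "attP", "attL", "attR"))
    cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}
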