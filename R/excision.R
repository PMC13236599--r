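## Long-read detection of proviral activation: attP-spanning reads
## (circularization), fold-back reads at the palindromic telRL site
## (hairpin linearization), and coverage enrichment (replication).

#' Detect attP-spanning reads
#'
#' A read from the excised circle crosses the re-formed attP junction:
#' its anchors jump from the EVE right terminus back to the EVE left
#' terminus. Reads whose consecutive anchors (same strand, adjacent in
#' the read) map within `D` bp of the right terminus and then within `D`
#' bp of the left terminus are reported.
#'
#' @param reads named character vector of reads.
#' @param integrated_ref named DNA string (the EVE-bearing haplotype).
#' @param eve_interval numeric `(start, end)`, 0-based half-open EVE
#'   interval on the reference (from a junction record or truth).
#' @param tol maximum read-coordinate gap between the two anchors
#'   (default 50); overlaps up to 20 bp are allowed.
#' @param D terminus proximity window in bp (default 500).
#' @param k anchor seed length (default 15).
#' @param anchors optional precomputed per-read anchor tables from an
#'   earlier detector call against the same reference.
#' @return data frame of class `span_events`: `read_id`,
#'   `read_junction` (read offset of the junction), `ref_from`
#'   (right-terminus coordinate), `ref_to` (left-terminus coordinate),
#'   `strand`.
#' @export
detect_attP_spanning <- function(reads, integrated_ref, eve_interval,
                                 tol = 50L, D = 500L, k = 15L,
                                 anchors = NULL) {
  es <- eve_interval[1]; ee <- eve_interval[2]
  if (is.null(anchors)) anchors <- read_anchors(reads, integrated_ref, k)
  out <- list()
  for (ri in seq_along(reads)) {
    a <- anchors[[ri]]
    if (nrow(a) < 2) next
    a <- a[order(a$query_start), ]
    for (i in seq_len(nrow(a) - 1)) {
      for (j in (i + 1):nrow(a)) {
        p <- a[i, ]; q <- a[j, ]
        if (p$strand != q$strand) next
        gap <- q$query_start - (p$query_start + p$length)
        if (gap > tol || gap < -20L) next
        if (p$strand == "+") {
          from_right <- abs((p$ref_start + p$length) - ee) <= D
          to_left <- abs(q$ref_start - es) <= D
        } else {
          from_right <- abs(p$ref_start - es) <= D
          to_left <- abs((q$ref_start + q$length) - ee) <= D
        }
        if (from_right && to_left) {
          out[[length(out) + 1L]] <- data.frame(
            read_id = names(reads)[ri] %||% as.character(ri),
            read_junction = p$query_start + p$length,
            ref_from = if (p$strand == "+") p$ref_start + p$length
                       else q$ref_start + q$length,
            ref_to = if (p$strand == "+") q$ref_start else p$ref_start,
            strand = p$strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), read_junction = integer(),
               ref_from = integer(), ref_to = integer(),
               strand = character(), stringsAsFactors = FALSE)
  res <- res[!duplicated(res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("span_events", "data.frame")
  res
}

#' Detect fold-back (sense/antisense) reads
#'
#' A read across a covalently closed hairpin end maps in one orientation
#' for part of its length, then reverts and maps antisense over the same
#' reference interval. For each read the best pair of opposite-strand
#' anchor blocks with overlapping reference footprints (>= 50% of the
#' shorter arm, excluding inter-locus chimeras) is located; the
#' reversion coordinate is the midpoint of the two blocks' innermost
#' read edges projected onto the reference through the sense anchor,
#' which is unbiased for a staggered apex.
#'
#' @param reads named character vector of reads.
#' @param ref named DNA string.
#' @param min_arm minimum arm length (default 100).
#' @param k anchor seed length (default 15).
#' @param anchors optional precomputed per-read anchor tables.
#' @return data frame of class `foldback_events`: `read_id`,
#'   `reversion_coord`, `left_arm_len`, `right_arm_len`, `strand_order`.
#' @export
detect_foldback <- function(reads, ref, min_arm = 100L, k = 15L,
                            anchors = NULL) {
  if (min_arm < k) stop_input("min_arm must be >= k")
  if (is.null(anchors)) anchors <- read_anchors(reads, ref, k)
  out <- list()
  for (ri in seq_along(reads)) {
    a <- anchors[[ri]]
    plus <- a[a$strand == "+" & a$length >= min_arm, , drop = FALSE]
    minus <- a[a$strand == "-" & a$length >= min_arm, , drop = FALSE]
    if (nrow(plus) == 0 || nrow(minus) == 0) next
    best <- NULL
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        p <- plus[i, ]; m <- minus[j, ]
        ov <- min(p$ref_start + p$length, m$ref_start + m$length) -
          max(p$ref_start, m$ref_start)
        if (ov < 0.5 * min(p$length, m$length)) next
        sc <- min(p$length, m$length)
        if (is.null(best) || sc > best$sc) best <- list(p = p, m = m, sc = sc)
      }
    }
    if (is.null(best)) next
    p <- best$p; m <- best$m
    if (p$query_start <= m$query_start) {
      first <- p; second <- m; order_str <- "+-"
    } else {
      first <- m; second <- p; order_str <- "-+"
    }
    flip_read <- (first$query_start + first$length + second$query_start) / 2
    rev_coord <- p$ref_start + (flip_read - p$query_start)
    out[[length(out) + 1L]] <- data.frame(
      read_id = names(reads)[ri] %||% as.character(ri),
      reversion_coord = rev_coord,
      left_arm_len = first$length, right_arm_len = second$length,
      strand_order = order_str, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), reversion_coord = numeric(),
               left_arm_len = integer(), right_arm_len = integer(),
               strand_order = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("foldback_events", "data.frame")
  res
}

#' Cluster fold-back reversion coordinates
#'
#' Single-linkage clustering of reversion coordinates at the given
#' radius; the largest cluster's median is the consensus reversion site.
#'
#' @param events a `foldback_events` data frame (non-empty).
#' @param radius linkage radius in bp (default 10).
#' @return list with `consensus_coord`, `support`, `spread`
#'   (coordinate range of the main cluster) and `clusters` (all
#'   clusters, largest first).
#' @export
cluster_reversions <- function(events, radius = 10L) {
  if (nrow(events) == 0) stop_contract("no fold-back events to cluster")
  x <- sort(events$reversion_coord)
  breaks <- which(diff(x) > radius)
  id <- cumsum(c(1L, as.integer(seq_along(x)[-1] %in% (breaks + 1L))))
  cl <- split(x, id)
  sizes <- lengths(cl)
  ord <- order(-sizes)
  cl <- cl[ord]
  main <- cl[[1]]
  list(consensus_coord = median(main), support = length(main),
       spread = diff(range(main)),
       clusters = lapply(cl, function(v)
         list(coord = median(v), support = length(v),
              spread = diff(range(v)))))
}

#' Locate the palindromic telRL core near a reversion consensus
#'
#' Searches a window around the consensus reversion coordinate for the
#' even-length reverse-complement-symmetric core whose center is nearest
#' the consensus (ties broken leftmost), and annotates the surrounding
#' inverted repeat.
#'
#' @param consensus_coord consensus reversion coordinate (0-based
#'   boundary).
#' @param ref named DNA string.
#' @param window search half-width in bp (default 50).
#' @param core_min,core_max even palindrome length bounds (defaults 4
#'   and 12).
#' @param ir_window half-width around the core in which to annotate the
#'   larger inverted repeat (default 60).
#' @return an object of class `telomere_site` (list with `core_start`,
#'   `core_end`, `core_seq`, `palindrome_len`, `apex_coord`,
#'   `outer_ir`), or `NULL` when no qualifying palindrome exists in the
#'   window.
#' @export
locate_telrl <- function(consensus_coord, ref, window = 50L, core_min = 4L,
                         core_max = 12L, ir_window = 60L) {
  if (window < core_max) stop_input("window must be >= core_max")
  s <- unname(ref[1])
  n <- nchar(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", v)
  cc <- as.integer(round(consensus_coord))
  centers <- max(1L, cc - window):min(n - 1L, cc + window)
  cand <- NULL
  for (c0 in centers) {
    ## even palindrome centered at boundary c0: s[c0-j-1] pairs s[c0+j]
    m <- 0L
    while (c0 - m >= 1L && c0 + m + 1L <= n &&
           v[c0 + m + 1L] == comp[c0 - m]) {
      m <- m + 1L
      if (2L * m >= core_max) break
    }
    plen <- 2L * m
    if (plen >= core_min) {
      d <- abs(c0 - consensus_coord)
      if (is.null(cand) || d < cand$d - 1e-9) {
        cand <- list(c0 = c0, plen = min(plen, core_max), d = d)
      }
    }
  }
  if (is.null(cand)) return(NULL)
  half <- cand$plen %/% 2L
  core_start <- cand$c0 - half
  core_end <- cand$c0 + half
  win_lo <- max(0L, core_start - ir_window)
  win <- subseq0(s, win_lo, min(n, core_end + ir_window))
  ir <- find_inverted_repeats(win, min_arm = 6L, max_loop = 2L * ir_window,
                              max_mismatch = 0L)
  if (nrow(ir) > 0) {
    ir$left_start <- ir$left_start + win_lo
    ir$left_end <- ir$left_end + win_lo
    ir$right_start <- ir$right_start + win_lo
    ir$right_end <- ir$right_end + win_lo
    ## the repeat must bracket the core
    ir <- ir[ir$left_end <= core_start & ir$right_start >= core_end, ,
             drop = FALSE]
    ir <- ir[order(-ir$arm_len), , drop = FALSE]
  }
  structure(list(core_start = core_start, core_end = core_end,
                 core_seq = subseq0(s, core_start, core_end),
                 palindrome_len = cand$plen, apex_coord = cand$c0,
                 outer_ir = if (nrow(ir) > 0) ir[1, ] else NULL),
            class = "telomere_site")
}

#' @export
print.telomere_site <- function(x, ...) {
  cat(sprintf("telomere_site: %d-bp palindromic core '%s' at [%d, %d)\n",
              x$palindrome_len, x$core_seq, x$core_start, x$core_end))
  if (!is.null(x$outer_ir))
    cat(sprintf("  within inverted repeat: arms %d bp, loop %d bp\n",
                x$outer_ir$arm_len, x$outer_ir$loop_len))
  invisible(x)
}

#' Coverage enrichment of the EVE locus
#'
#' Per-base depth from each read's best anchor chain; returns the median
#' depth inside the EVE interval divided by the median depth outside.
#'
#' @param reads named character vector of reads.
#' @param ref named DNA string.
#' @param eve_interval numeric `(start, end)` on the reference.
#' @param k anchor seed length (default 15).
#' @param anchors optional precomputed per-read anchor tables.
#' @return the coverage ratio, or `NA` (with a warning) when the host
#'   flank has zero median coverage.
#' @export
coverage_ratio <- function(reads, ref, eve_interval, k = 15L,
                           anchors = NULL) {
  n <- nchar(unname(ref[1]))
  if (is.null(anchors)) anchors <- read_anchors(reads, ref, k)
  depth <- numeric(n)
  for (ri in seq_along(reads)) {
    ch <- best_chain_from_anchors(anchors[[ri]], n, k)
    for (i in seq_len(nrow(ch))) {
      a <- ch$ref_start[i] + 1L
      b <- ch$ref_start[i] + ch$length[i]
      depth[a:b] <- depth[a:b] + 1
    }
  }
  inside <- depth[(eve_interval[1] + 1L):eve_interval[2]]
  outside <- depth[-((eve_interval[1] + 1L):eve_interval[2])]
  if (length(outside) == 0 || median(outside) == 0) {
    warning("zero host coverage: ratio undefined")
    return(NA_real_)
  }
  median(inside) / median(outside)
}

#' Summarize excision evidence
#'
#' @param span a `span_events` data frame.
#' @param foldback a `foldback_events` data frame.
#' @param telsite a `telomere_site` or `NULL`.
#' @param cov coverage ratio from [coverage_ratio()].
#' @param min_span,min_fb minimum supporting reads per signature
#'   (default 3 each).
#' @param min_ratio minimum coverage ratio called as replication
#'   (default 2).
#' @return an object of class `excision_report`: counts, telRL
#'   coordinates, coverage ratio and the three verdict flags
#'   (`circularization`, `linearization`, `replication`).
#' @export
summarize_excision <- function(span, foldback, telsite, cov,
                               min_span = 3L, min_fb = 3L, min_ratio = 2) {
  n_span <- nrow(span)
  n_fb <- nrow(foldback)
  structure(list(
    n_span = n_span, n_foldback = n_fb,
    telrl_coord = if (!is.null(telsite)) telsite$core_start else NA_integer_,
    palindrome_len = if (!is.null(telsite)) telsite$palindrome_len
                     else NA_integer_,
    coverage_ratio = cov,
    flags = list(
      circularization = n_span >= min_span,
      linearization = !is.null(telsite) && n_fb >= min_fb,
      replication = !is.na(cov) && cov >= min_ratio),
    thresholds = list(min_span = min_span, min_fb = min_fb,
                      min_ratio = min_ratio)),
    class = "excision_report")
}

#' @export
print.excision_report <- function(x, ...) {
  cat("excision_report\n")
  cat(sprintf("  attP-spanning reads: %d (circularization: %s)\n",
              x$n_span, x$flags$circularization))
  cat(sprintf("  fold-back reads:     %d (linearization:  %s)\n",
              x$n_foldback, x$flags$linearization))
  if (!is.na(x$telrl_coord))
    cat(sprintf("  telRL: %d-bp palindrome at %d\n", x$palindrome_len,
                x$telrl_coord))
  cat(sprintf("  coverage ratio:      %.2f (replication:    %s)\n",
              if (is.na(x$coverage_ratio)) NA else x$coverage_ratio,
              x$flags$replication))
  invisible(x)
}
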