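## Terminus position-profiles, genome scanning, hit filtering and
## deduplication, sequence logos, attB/attP consensus inference and
## repeat finding.

base_index <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)

## 4 x L count matrix from equal-length ungapped sequences.
count_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop_input("sequences must have equal length")
  if (L == 0) stop_input("sequences must be non-empty")
  m <- matrix(0L, 4, L, dimnames = list(DNA_BASES, NULL))
  for (s in seqs) {
    idx <- base_index(s)
    keep <- !is.na(idx)
    j <- which(keep)
    m[cbind(idx[keep], j)] <- m[cbind(idx[keep], j)] + 1L
  }
  m
}

#' Trim an alignment to its conserved terminal region
#'
#' Keeps the maximal run of columns, anchored at one alignment end, in
#' which occupancy (non-gap fraction) and information content both meet
#' their thresholds. This mirrors the manual trimming of terminus
#' alignments to the well-conserved terminal blocks before profile
#' construction.
#'
#' @param aligned_seqs character vector of equal-length rows; gaps `"-"`.
#' @param occupancy_min minimum non-gap fraction per kept column
#'   (default 0.5).
#' @param ic_min minimum per-column information content in bits
#'   (default 0).
#' @param anchor `"left"`, `"right"` or `"best"` (the longer of the two
#'   terminal-anchored runs; default).
#' @return character vector of trimmed rows (attribute `kept_columns`
#'   gives the retained column indices).
#' @export
trim_alignment <- function(aligned_seqs, occupancy_min = 0.5, ic_min = 0,
                           anchor = c("best", "left", "right")) {
  anchor <- match.arg(anchor)
  if (length(aligned_seqs) == 0) stop_input("empty alignment")
  L <- unique(nchar(aligned_seqs))
  if (length(L) != 1) stop_input("alignment rows must have equal length")
  if (length(aligned_seqs) == 1) {
    warning("single-row alignment returned unchanged")
    out <- aligned_seqs
    attr(out, "kept_columns") <- seq_len(L)
    return(out)
  }
  mat <- do.call(rbind, strsplit(aligned_seqs, "", fixed = TRUE))
  occ <- colMeans(mat != "-")
  ic <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    p <- table(factor(col, levels = DNA_BASES)) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  ok <- occ >= occupancy_min & ic >= ic_min
  run_from_left <- if (ok[1]) {
    w <- which(!ok); if (length(w) == 0) L else w[1] - 1L
  } else 0L
  run_from_right <- if (ok[L]) {
    w <- which(!rev(ok)); if (length(w) == 0) L else w[1] - 1L
  } else 0L
  keep <- switch(anchor,
    left = seq_len(run_from_left),
    right = if (run_from_right > 0) (L - run_from_right + 1L):L else integer(0),
    best = if (run_from_left >= run_from_right) seq_len(run_from_left)
           else (L - run_from_right + 1L):L)
  if (length(keep) == 0) stop_input("no terminal column passes the filters")
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  attr(out, "kept_columns") <- keep
  out
}

#' Build a terminus position log-odds profile
#'
#' An ungapped position profile of EVE terminal sequences: per-column
#' base counts with pseudocount `alpha`, and log-odds
#' `log2(((count + alpha) / (n + 4 alpha)) / background)`.
#'
#' @param seqs equal-length ungapped DNA strings (post-trim).
#' @param side `"left"` or `"right"`: which EVE terminus the profile
#'   models. The terminal (junction-proximal) model column is column 1
#'   for a left-end profile and column L for a right-end profile.
#' @param alpha pseudocount (default 1).
#' @param background named base-frequency vector (default uniform).
#' @return an object of class `terminus_profile`: list with `side`, `L`,
#'   `counts`, `alpha`, `background`, `log_odds`, `consensus`, `nseq`.
#' @export
build_profile <- function(seqs, side = c("left", "right"), alpha = 1,
                          background = c(A = .25, C = .25, G = .25, T = .25)) {
  side <- match.arg(side)
  counts <- count_matrix(seqs)
  lo <- profile_log_odds(counts, alpha, background)
  cons <- paste(DNA_BASES[apply(counts + alpha, 2, which.max)], collapse = "")
  structure(list(side = side, L = ncol(counts), counts = counts,
                 alpha = alpha, background = background[DNA_BASES],
                 log_odds = lo, consensus = cons, nseq = length(seqs)),
            class = "terminus_profile")
}

profile_log_odds <- function(counts, alpha, background) {
  n <- colSums(counts)
  freq <- sweep(counts + alpha, 2, n + 4 * alpha, "/")
  log2(freq / background[DNA_BASES])
}

#' @export
print.terminus_profile <- function(x, ...) {
  cat(sprintf("terminus_profile (%s end): %d columns from %d sequences, alpha=%g\n",
              x$side, x$L, x$nseq, x$alpha))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

## Score all full windows of `lo` (4 x L) against integer-coded contig.
score_windows <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + lo[cbind(codes[j:(j + nw - 1L)], j)]
  }
  sc
}

#' Scan contigs with a terminus profile
#'
#' Slides the profile over both strands of every contig, scoring each
#' window as the sum of per-column log-odds; with `allow_partial`,
#' truncated model windows hanging over contig edges are scored as well
#' (their missing terminal-side columns are reported as
#' `dist_to_model_end`). Overlapping hits are resolved greedily by
#' score.
#'
#' @param profile a `terminus_profile`.
#' @param contigs named character vector of DNA strings.
#' @param score_min minimum reported score in bits; default 0.6 times
#'   the maximum achievable profile score.
#' @param allow_partial score truncated windows at contig edges
#'   (default TRUE).
#' @param background `"profile"` (use the profile's stored log-odds) or
#'   `"contig"` (recompute log-odds against each scanned contig's base
#'   composition; default, matching screens of genomes whose composition
#'   differs from the training set).
#' @return data frame of class `terminus_hits`: `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `hit_len`,
#'   `dist_to_model_end`.
#' @export
scan_genome <- function(profile, contigs, score_min = NULL,
                        allow_partial = TRUE,
                        background = c("contig", "profile")) {
  stopifnot(inherits(profile, "terminus_profile"))
  background <- match.arg(background)
  out <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci] %||% as.character(ci)
    s <- unname(contigs[ci])
    lo <- profile$log_odds
    if (background == "contig") {
      tb <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                         levels = DNA_BASES))
      bg <- as.numeric(tb) / sum(tb)
      names(bg) <- DNA_BASES
      bg[bg == 0] <- 1e-6
      lo <- profile_log_odds(profile$counts, profile$alpha, bg)
    }
    L <- ncol(lo)
    smin <- if (is.null(score_min)) 0.6 * sum(apply(lo, 2, max)) else score_min
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") s else revcomp(s)
      codes <- base_index(seqs)
      n <- length(codes)
      sc <- score_windows(codes, lo)
      hits <- which(sc >= smin)
      for (h in hits) {
        st <- h - 1L
        out[[length(out) + 1L]] <- data.frame(
          contig = cname,
          start = if (strand == "+") st else n - st - L,
          end = if (strand == "+") st + L else n - st,
          strand = strand, score = sc[h], hit_len = L,
          dist_to_model_end = 0L, stringsAsFactors = FALSE)
      }
      if (allow_partial && n >= 1) {
        for (t in seq_len(min(L - 1L, n))) {
          ## model right part (columns L-t+1..L) at contig start
          sc1 <- sum(lo[cbind(codes[seq_len(t)], (L - t + 1L):L)])
          if (sc1 >= smin) {
            miss_left <- L - t
            out[[length(out) + 1L]] <- data.frame(
              contig = cname,
              start = if (strand == "+") 0L else n - t,
              end = if (strand == "+") t else n,
              strand = strand, score = sc1, hit_len = t,
              dist_to_model_end =
                if (profile$side == "left") miss_left else 0L,
              stringsAsFactors = FALSE)
          }
          ## model left part (columns 1..t) at contig end
          sc2 <- sum(lo[cbind(codes[(n - t + 1L):n], seq_len(t))])
          if (sc2 >= smin) {
            miss_right <- L - t
            out[[length(out) + 1L]] <- data.frame(
              contig = cname,
              start = if (strand == "+") n - t else 0L,
              end = if (strand == "+") n else t,
              strand = strand, score = sc2, hit_len = t,
              dist_to_model_end =
                if (profile$side == "right") miss_right else 0L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(), hit_len = integer(),
               dist_to_model_end = integer(), stringsAsFactors = FALSE)
  hits <- drop_overlaps(hits)
  rownames(hits) <- NULL
  attr(hits, "side") <- profile$side
  class(hits) <- c("terminus_hits", "data.frame")
  hits
}

## Greedy non-overlap selection by descending score within each contig.
drop_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  hits <- hits[order(-hits$score, hits$contig, hits$start), ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prior <- hits[keep, ]
      same <- prior$contig == hits$contig[i]
      if (any(same & prior$start < hits$end[i] & hits$start[i] < prior$end))
        ok <- FALSE
    }
    keep[i] <- ok
  }
  hits <- hits[keep, ]
  hits[order(hits$contig, hits$start), ]
}

#' Filter terminus hits by length and distance to the model's terminal end
#'
#' Retains hits of at least `min_len` bp that intersect the profile
#' within `max_dist` bp of its terminal end (both bounds inclusive).
#' Order-preserving and idempotent.
#'
#' @param hits a `terminus_hits` data frame.
#' @param min_len minimum hit length in bp (default 80).
#' @param max_dist maximum distance to the model's terminal column in bp
#'   (default 50).
#' @return the filtered hits.
#' @export
filter_hits <- function(hits, min_len = 80L, max_dist = 50L) {
  keep <- hits$hit_len >= min_len & hits$dist_to_model_end <= max_dist
  out <- hits[keep, , drop = FALSE]
  attr(out, "side") <- attr(hits, "side")
  class(out) <- class(hits)
  out
}

#' Collapse terminus hits with identical flanking host sequence
#'
#' Hits whose flanking host sequence (upstream of a left-end hit,
#' downstream of a right-end hit, on the hit's strand) is string-identical
#' are reduced to a single representative (first by contig, then
#' coordinate) — duplicates typically represent the same element shared
#' between closely related assemblies. Flanks truncated by contig edges
#' are compared as-is.
#'
#' @param hits a `terminus_hits` data frame (attribute `side` set by
#'   [scan_genome()], or supply `side`).
#' @param contigs named character vector the hits refer to.
#' @param flank_w flank width in bp (default 100).
#' @param side `"left"` or `"right"`; defaults to the hits' attribute.
#' @return the deduplicated hits.
#' @export
dedup_flanks <- function(hits, contigs, flank_w = 100L,
                         side = attr(hits, "side")) {
  if (flank_w <= 0) stop_input("flank_w must be positive")
  if (is.null(side)) stop_input("side missing: pass side= or use scan_genome hits")
  if (nrow(hits) == 0) return(hits)
  flanks <- vapply(seq_len(nrow(hits)), function(i) {
    s <- unname(contigs[[hits$contig[i]]])
    n <- nchar(s)
    upstream <- xor(side == "right", hits$strand[i] == "-")
    ## upstream flank for left ends, downstream for right ends
    if (!upstream) {
      f <- subseq0(s, max(0L, hits$start[i] - flank_w), hits$start[i])
    } else {
      f <- subseq0(s, hits$end[i], min(n, hits$end[i] + flank_w))
    }
    if (hits$strand[i] == "-") f <- revcomp(f)
    f
  }, character(1))
  ord <- order(hits$contig, hits$start)
  first <- ord[!duplicated(flanks[ord])]
  out <- hits[sort(first), , drop = FALSE]
  attr(out, "side") <- side
  class(out) <- class(hits)
  out
}

#' Per-column base frequencies and information content
#'
#' @param seqs equal-length DNA strings.
#' @return an object of class `logo_matrix`: list with `freq` (4 x L),
#'   `ic` (bits per column, `2 - H`), `nseq`. No small-sample correction
#'   is applied.
#' @export
make_logo <- function(seqs) {
  counts <- count_matrix(seqs)
  n <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n, 1L), "/")
  H <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, ic = 2 - H, nseq = length(seqs)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix: %d columns from %d sequences\n",
              ncol(x$freq), x$nseq))
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Plot a sequence logo
#'
#' Thin base-graphics rendering of a [make_logo()] matrix: stacked
#' letters scaled by frequency times column information content.
#'
#' @param x a `logo_matrix`.
#' @param ... ignored.
#' @export
plot.logo_matrix <- function(x, ...) {
  L <- ncol(x$freq)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, 2), xlab = "position",
                 ylab = "bits", main = "sequence logo", xaxs = "i")
  cols <- c(A = "forestgreen", C = "royalblue", G = "orange", T = "firebrick")
  for (j in seq_len(L)) {
    y <- 0
    ord <- order(x$freq[, j])
    for (b in rownames(x$freq)[ord]) {
      h <- x$freq[b, j] * x$ic[j]
      if (h > 1e-3) {
        graphics::text(j, y + h / 2, b, cex = 0.5 + 2 * h, col = cols[b])
        y <- y + h
      }
    }
  }
  invisible(x)
}

#' Infer attB/attP consensus and the recombination core
#'
#' Given attL and attR sequence sets aligned on their host-virus
#' junction, finds the maximal run of columns ending at the junction in
#' which the attL pre-junction (host attB side) consensus and the attR
#' pre-junction (viral terminus) consensus agree: the shared core plus
#' any extended homology. The attB consensus is rebuilt as attL host
#' flank + core + attR host flank, and attP as attR viral terminus +
#' core + attL viral start.
#'
#' @param attL_seqs,attR_seqs equal-length sequence sets.
#' @param junction_L,junction_R number of pre-junction columns (the
#'   junction lies after this many bases); default half the width.
#' @param core_max longest homology run reported (default 10).
#' @return an object of class `att_consensus`: list with `attB`, `attP`,
#'   `core`, `core_len`, and the two consensus strings.
#' @export
infer_att_consensus <- function(attL_seqs, attR_seqs,
                                junction_L = NULL, junction_R = NULL,
                                core_max = 10L) {
  consL <- consensus_string(attL_seqs)
  consR <- consensus_string(attR_seqs)
  jL <- junction_L %||% (nchar(consL) %/% 2L)
  jR <- junction_R %||% (nchar(consR) %/% 2L)
  preL <- substr(consL, 1, jL); preR <- substr(consR, 1, jR)
  core_len <- min(common_suffix_len(preL, preR), core_max, jL, jR)
  if (core_len == 0)
    warning("junction columns disagree: core length 0")
  core <- if (core_len > 0)
    substr(preL, jL - core_len + 1L, jL) else ""
  attB <- paste0(substr(consL, 1, jL),
                 substr(consR, jR + 1L, nchar(consR)))
  attP <- paste0(substr(consR, 1, jR),
                 substr(consL, jL + 1L, nchar(consL)))
  structure(list(attB = attB, attP = attP, core = core,
                 core_len = core_len, attL_consensus = consL,
                 attR_consensus = consR),
            class = "att_consensus")
}

consensus_string <- function(seqs) {
  counts <- count_matrix(seqs)
  paste(DNA_BASES[apply(counts, 2, which.max)], collapse = "")
}

#' Find inverted or direct repeats in a sequence
#'
#' Enumerates maximal repeat arm pairs: for inverted repeats the right
#' arm reverse-complement-matches the left arm across a loop of at most
#' `max_loop` bp with at most `max_mismatch` mismatches (perfect
#' palindromes are the `loop_len = 0` case); for direct repeats the two
#' arms match forward across a spacer.
#'
#' @param seq single DNA string.
#' @param min_arm minimum arm length (default 4).
#' @param max_loop maximum loop/spacer length (default 20).
#' @param max_mismatch maximum mismatches per arm pair (default 0).
#' @param kind `"inverted"` or `"direct"`.
#' @return data frame with `left_start`, `left_end`, `right_start`,
#'   `right_end` (0-based half-open arms), `kind`, `arm_len`, `loop_len`,
#'   `mismatches`, `at_fraction`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 4L, max_loop = 20L,
                                  max_mismatch = 0L,
                                  kind = c("inverted", "direct")) {
  kind <- match.arg(kind)
  if (min_arm <= 0 || max_loop < 0) stop_input("parameters must be positive")
  s <- unname(seq[1])
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  comp <- chartr("ACGT", "TGCA", v)
  if (kind == "direct") return(find_direct_repeats(v, min_arm, max_loop,
                                                   max_mismatch))
  out <- list()
  for (loop in 0:max_loop) {
    ## left arm ends at position i (0-based, exclusive); right arm starts
    ## at i + loop
    for (i in seq_len(max(0L, n - loop - 1L))) {
      li <- i            # 1-based index of last left-arm base
      ri <- i + loop + 1L  # 1-based index of first right-arm base
      if (ri > n) next
      mm <- 0L; a <- 0L
      while (li - a >= 1L && ri + a <= n) {
        match_ok <- if (kind == "inverted") v[ri + a] == comp[li - a]
                    else v[ri + a] == v[li - a]
        if (!match_ok) {
          if (mm + 1L > max_mismatch) break
          mm <- mm + 1L
        }
        a <- a + 1L
      }
      ## trim trailing mismatches
      while (a > 0L) {
        last_ok <- if (kind == "inverted") v[ri + a - 1L] == comp[li - a + 1L]
                   else v[ri + a - 1L] == v[li - a + 1L]
        if (last_ok) break
        a <- a - 1L; mm <- mm - 1L
      }
      if (a >= min_arm) {
        arm_bases <- c(v[(li - a + 1L):li], v[ri:(ri + a - 1L)])
        out[[length(out) + 1L]] <- data.frame(
          left_start = li - a, left_end = li,
          right_start = ri - 1L, right_end = ri - 1L + a,
          kind = kind, arm_len = a, loop_len = loop, mismatches = mm,
          at_fraction = mean(arm_bases %in% c("A", "T")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      kind = character(), arm_len = integer(),
                      loop_len = integer(), mismatches = integer(),
                      at_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  ## keep arm-maximal hits only: drop a hit nested inside another with the
  ## same loop midpoint and kind
  key <- paste(res$left_end + res$loop_len / 2, res$kind)
  keep <- unlist(lapply(split(seq_len(nrow(res)), key), function(idx) {
    idx[which.max(res$arm_len[idx])]
  }))
  res <- res[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Direct (forward-parallel) repeat enumeration: copies start g bp apart,
## arms extend forward; spacer = g - arm_len.
find_direct_repeats <- function(v, min_arm, max_loop, max_mismatch) {
  n <- length(v)
  out <- list()
  for (g in seq_len(n - 1)) {
    p <- 1L
    while (p + g <= n) {
      a <- 0L; mm <- 0L
      while (p + g + a <= n) {
        if (v[p + a] != v[p + g + a]) {
          if (mm + 1L > max_mismatch) break
          mm <- mm + 1L
        }
        a <- a + 1L
      }
      while (a > 0L && v[p + a - 1L] != v[p + g + a - 1L]) {
        a <- a - 1L; mm <- mm - 1L
      }
      arm <- min(a, g)
      loop <- g - arm
      if (arm >= min_arm && loop <= max_loop) {
        arm_bases <- c(v[p:(p + arm - 1L)], v[(p + g):(p + g + arm - 1L)])
        out[[length(out) + 1L]] <- data.frame(
          left_start = p - 1L, left_end = p - 1L + arm,
          right_start = p - 1L + g, right_end = p - 1L + g + arm,
          kind = "direct", arm_len = arm, loop_len = loop,
          mismatches = sum(v[p:(p + arm - 1L)] !=
                             v[(p + g):(p + g + arm - 1L)]),
          at_fraction = mean(arm_bases %in% c("A", "T")),
          stringsAsFactors = FALSE)
      }
      p <- p + max(a, 1L)
    }
  }
  if (length(out) == 0) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      kind = character(), arm_len = integer(),
                      loop_len = integer(), mismatches = integer(),
                      at_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$left_start, -res$arm_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}
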