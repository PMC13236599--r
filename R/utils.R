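#' @importFrom stats median rbinom rnorm rpois runif setNames pchisq qnorm
#' @importFrom utils write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

## All coordinates inside the package are 0-based, half-open [start, end).
## 1-based coordinates appear only at the GFF3 boundary.

#' Extract a 0-based half-open subsequence
#'
#' @param x single DNA string.
#' @param start,end 0-based half-open interval.
#' @return character substring; empty string when `start >= end`.
#' @keywords internal
subseq0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' G+C fraction of a DNA string
#'
#' @param x single DNA string.
#' @return fraction of G or C bases.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0) return(NA_real_)
  gc <- nchar(gsub("[AT]", "", x))
  gc / n
}

#' Is a DNA string its own reverse complement?
#'
#' @param x single DNA string.
#' @return logical.
#' @export
is_palindrome <- function(x) {
  nchar(x) > 0 && nchar(x) %% 2 == 0 && identical(x, revcomp(x))
}

## Evaluate expr with a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Random DNA string at a target GC; vectorised over length.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## AT-rich random arm used for attachment-site flanking repeats.
random_at_rich <- function(n, at = 0.8) random_dna(n, gc = 1 - at)

## Replace bases of `x` at 0-based position `pos` with string `s`.
splice_in <- function(x, pos, s) {
  paste0(subseq0(x, 0L, pos), s, subseq0(x, pos + nchar(s), nchar(x)))
}

## Insert string `s` into `x` before 0-based position `pos` (no overwrite).
insert_at <- function(x, pos, s) {
  paste0(subseq0(x, 0L, pos), s, subseq0(x, pos, nchar(x)))
}

## Length of the longest common suffix of two strings.
common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b); n <- min(na, nb)
  if (n == 0) return(0L)
  av <- substring(a, na - n + seq_len(n), na - n + seq_len(n))
  bv <- substring(b, nb - n + seq_len(n), nb - n + seq_len(n))
  eq <- rev(av == bv)
  if (!eq[1]) return(0L)
  w <- which(!eq)
  if (length(w) == 0) n else w[1] - 1L
}

## Length of the longest common prefix of two strings.
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- substring(a, seq_len(n), seq_len(n))
  bv <- substring(b, seq_len(n), seq_len(n))
  eq <- av == bv
  if (!eq[1]) return(0L)
  w <- which(!eq)
  if (length(w) == 0) n else w[1] - 1L
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("evetrace_input_error", "error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("evetrace_contract_error", "error")))
}

## Build a truth-set data frame (0-based half-open coordinates).
truth_df <- function(genome_id = character(), feature = character(),
                     start = integer(), end = integer(), detail = character()) {
  data.frame(genome_id = genome_id, feature = feature,
             start = as.integer(start), end = as.integer(end),
             detail = detail, stringsAsFactors = FALSE)
}
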