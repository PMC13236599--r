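## Standard-format I/O. Sequences travel as named character vectors;
## internal coordinates are 0-based half-open (BED keeps them, GFF3 is
## converted to 1-based inclusive on write).

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercased DNA strings; empty
#'   vector for an empty file.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path file path; lines wrap at 80 columns.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path file path.
#' @return named character vector of reads with attribute `qualities`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) | seq_along(lines) %% 4 != 1]
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stop_input("truncated FASTQ record at record ",
               length(lines) %/% 4 + 1)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(nchar(seqs) != nchar(quals)))
    stop_input("sequence/quality length mismatch at record ",
               which(nchar(seqs) != nchar(quals))[1])
  out <- setNames(seqs, ids)
  attr(out, "qualities") <- quals
  out
}

#' Write reads as FASTQ
#'
#' @param reads named character vector; qualities from the `qualities`
#'   attribute, or constant `'I'` when absent (the error-free
#'   convention).
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  quals <- attr(reads, "qualities")
  if (is.null(quals))
    quals <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+", quals[i]),
               con)
  }
  invisible(path)
}

check_features <- function(features) {
  stopifnot(all(c("contig", "start", "end", "name") %in% names(features)))
  if (any(features$start < 0)) stop_input("negative coordinates")
  if (is.null(features$strand)) features$strand <- "+"
  if (is.null(features$score)) features$score <- 0
  features[order(features$contig, features$start), , drop = FALSE]
}

#' Write features as BED6
#'
#' Internal 0-based half-open coordinates are BED's native convention;
#' the feature type goes in the name column.
#'
#' @param features data frame with `contig`, `start`, `end`, `name` and
#'   optional `score`, `strand`.
#' @param path file path.
#' @export
write_bed <- function(features, path) {
  f <- check_features(features)
  write.table(f[, c("contig", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path file path.
#' @return data frame with 0-based half-open `start`/`end`.
#' @export
read_bed <- function(path) {
  f <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(f)[1:6] <- c("contig", "start", "end", "name", "score", "strand")
  f
}

#' Write features as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open
#' convention to GFF3's 1-based inclusive.
#'
#' @param features data frame as for [write_bed()]; optional `source`
#'   and `type` columns (defaults `"evetrace"` and `"region"`).
#' @param path file path.
#' @export
write_gff3 <- function(features, path) {
  f <- check_features(features)
  if (is.null(f$source)) f$source <- "evetrace"
  if (is.null(f$type)) f$type <- "region"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\tName=%s",
                   f$contig, f$source, f$type, f$start + 1L, f$end,
                   ifelse(is.na(f$score), ".", as.character(f$score)),
                   f$strand, f$name)
  writeLines(lines, con)
  invisible(path)
}

#' Write a progeny table as TSV
#'
#' @param table a `progeny_table`.
#' @param path file path.
#' @export
write_progeny_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a progeny table from TSV
#'
#' @param path file path.
#' @param loci locus column names (default: all logical columns).
#' @return a `progeny_table` data frame.
#' @export
read_progeny_table <- function(path, loci = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(loci))
    loci <- names(tab)[vapply(tab, is.logical, logical(1))]
  class(tab) <- c("progeny_table", "data.frame")
  attr(tab, "active_loci") <- character(0)
  tab
}

#' Convert a truth data frame to BED-style features
#'
#' @param truth truth data frame from the generators.
#' @return data frame ready for [write_bed()].
#' @export
truth_to_features <- function(truth) {
  data.frame(contig = truth$genome_id, start = truth$start, end = truth$end,
             name = truth$feature, score = 0, strand = "+",
             stringsAsFactors = FALSE)
}
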