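## Mendelian segregation, genotype-phenotype linkage, multi-locus
## combination frequencies, penetrance and qPCR relative copy number.

#' Chi-square test of EVE-symptom association (2 x 2)
#'
#' Pearson chi-square on a 2 x 2 presence/phenotype table with expected
#' counts from the margins, optionally with Yates continuity correction
#' (the default, matching the common statistical-environment default for
#' 2 x 2 tables).
#'
#' @param table 2 x 2 matrix of non-negative integer counts (rows: EVE
#'   present/absent; columns: symptomatic/asymptomatic).
#' @param correction apply Yates continuity correction (default TRUE).
#' @return an object of classes `linkage_result` and `htest` with
#'   `statistic`, `parameter` (df = 1), `p.value`, `observed`,
#'   `expected`.
#' @export
linkage_test <- function(table, correction = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop_input("table must be 2 x 2")
  if (any(tab < 0)) stop_input("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_contract("zero margin: association undefined")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(statistic = c(`X-squared` = chi2),
                 parameter = c(df = 1),
                 p.value = p, observed = tab, expected = E,
                 correction = correction,
                 method = paste0("Chi-squared test of EVE-symptom association",
                                 if (correction)
                                   " (Yates continuity correction)"),
                 data.name = deparse(substitute(table))),
            class = c("linkage_result", "htest"))
}

#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' @param counts observed class counts.
#' @param ratio expected ratio (e.g. `c(1, 1)`); normalized internally.
#' @return an object of classes `segregation_result` and `htest`
#'   (`df = classes - 1`).
#' @export
mendelian_test <- function(counts, ratio = rep(1, length(counts))) {
  if (length(counts) != length(ratio))
    stop_input("counts and ratio must have equal length")
  if (any(counts < 0) || any(ratio <= 0))
    stop_input("counts must be non-negative and ratio positive")
  E <- sum(counts) * ratio / sum(ratio)
  chi2 <- sum((counts - E)^2 / E)
  df <- length(counts) - 1L
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(statistic = c(`X-squared` = chi2),
                 parameter = c(df = df), p.value = p,
                 observed = counts, expected = E,
                 method = "Chi-squared goodness of fit to Mendelian ratio",
                 data.name = deparse(substitute(counts))),
            class = c("segregation_result", "htest"))
}

#' Expected genotype-class frequencies for a multi-locus cross
#'
#' Enumerates all genotype classes of hemizygous loci: each linkage
#' group (chromosome homolog pair) transmits one side with probability
#' 1/2, so unlinked loci contribute independent presence/absence factors
#' of 1/2 and homologue-exclusive pairs contribute exactly one of their
#' two members.
#'
#' @param loci data frame with `locus_id`, `chromosome_id`, `homolog`
#'   (as in [cross_spec()]).
#' @return named numeric vector mapping genotype class (loci present,
#'   `+`-separated; `"none"` for the empty class) to probability; sums
#'   to 1.
#' @export
combination_frequencies <- function(loci) {
  stopifnot(is.data.frame(loci))
  if (anyDuplicated(loci$locus_id))
    stop_input("locus appears in more than one position: contradictory spec")
  chroms <- split(loci, loci$chromosome_id)
  classes <- data.frame(label = "", p = 1, stringsAsFactors = FALSE)
  for (g in chroms) {
    outcomes <- lapply(c(0L, 1L), function(h) g$locus_id[g$homolog == h])
    new <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
      do.call(rbind, lapply(outcomes, function(present) {
        lab <- paste(c(strsplit(classes$label[i], "\\+")[[1]], present),
                     collapse = "+")
        data.frame(label = lab, p = classes$p[i] * 0.5,
                   stringsAsFactors = FALSE)
      }))
    }))
    classes <- new
  }
  classes$label <- vapply(classes$label, function(l) {
    parts <- setdiff(strsplit(l, "\\+")[[1]], "")
    if (length(parts) == 0) "none" else paste(sort(parts), collapse = "+")
  }, character(1))
  p <- tapply(classes$p, classes$label, sum)
  out <- as.numeric(p)
  names(out) <- names(p)
  out
}

#' Estimate penetrance of an active EVE locus
#'
#' Penetrance reconciles carrier status with observed symptoms: the
#' fraction of carriers of the active locus that are symptomatic, with a
#' Wilson score 95% interval.
#'
#' @param table a `progeny_table` from [simulate_cross()] (or any data
#'   frame with a logical locus column and a `phenotype` column).
#' @param active_locus name of the active locus column.
#' @return list with `estimate`, `lower`, `upper`, `carriers`,
#'   `symptomatic_carriers`.
#' @export
estimate_penetrance <- function(table, active_locus) {
  if (!active_locus %in% names(table))
    stop_input("locus '", active_locus, "' not in table")
  carriers <- table[[active_locus]]
  n <- sum(carriers)
  if (n == 0) stop_contract("no carriers of the active locus")
  x <- sum(carriers & table$phenotype == "symptomatic")
  ci <- wilson_interval(x, n)
  list(estimate = x / n, lower = ci[1], upper = ci[2], carriers = n,
       symptomatic_carriers = x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes; `n` trials; `conf` confidence level (default
#'   0.95).
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric `(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' qPCR relative copy number from quantification cycles
#'
#' Relative copy number by the delta-Cq method: `2^(Cq_reference -
#' Cq_target)`.
#'
#' @param cq_target Cq of the viral target (e.g. MCP).
#' @param cq_reference Cq of the host reference (e.g. 18S).
#' @return relative copy number (vectorized).
#' @export
relative_copy_number <- function(cq_target, cq_reference) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference)))
    stop_input("Cq values must be finite")
  2^(cq_reference - cq_target)
}

#' Cross-tabulate a locus against phenotype
#'
#' @param table a `progeny_table`.
#' @param locus locus column name.
#' @return 2 x 2 matrix (rows present/absent, columns
#'   symptomatic/asymptomatic) suitable for [linkage_test()].
#' @export
locus_phenotype_table <- function(table, locus) {
  if (!locus %in% names(table)) stop_input("locus '", locus, "' not in table")
  present <- factor(ifelse(table[[locus]], "present", "absent"),
                    levels = c("present", "absent"))
  pheno <- factor(table$phenotype, levels = c("symptomatic", "asymptomatic"))
  as.matrix(stats::xtabs(~ present + pheno))
}
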