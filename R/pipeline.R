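## End-to-end demonstration pipeline: simulate -> resolve junctions ->
## attachment sites -> excision signatures -> segregation genetics.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 10 kb host chromosome, a 6 kb EVE with the
#' standard terminal architecture, symptomatic read depths, and a
#' 200-progeny cross with one active locus among four unlinked EVEs.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a nested list, the `RunConfig`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(host_length = 10000L, host_gc = 0.5, eve_length = 6000L,
                    eve_gc = 0.52, site_fraction = 0.45,
                    symptomatic = TRUE,
                    depths = list(integrated = 4, circle = 10, hairpin = 10,
                                  host_background = 4),
                    read_length = c(800, 100), error_rate = 0),
    junctions = list(k = 15L, flank_w = 30L),
    excision = list(min_arm = 100L, min_span = 3L, min_fb = 3L,
                    min_ratio = 2, telrl_window = 50L, core_min = 4L,
                    core_max = 12L),
    cross = list(n_progeny = 200L, penetrance = 1,
                 loci = data.frame(
                   locus_id = c("EVEb", "EVEc", "EVEd", "EVEe"),
                   chromosome_id = c("chr06", "chr16", "chr26", "chr03"),
                   homolog = 0L, stringsAsFactors = FALSE),
                 active = "EVEc")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; missing blocks fall back to
#' [default_config()] values.
#'
#' @param path YAML file path.
#' @return a `RunConfig` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0)
    stop_input("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(base, cfg)
  if (is.list(out$cross$loci)) {
    out$cross$loci <- as.data.frame(out$cross$loci,
                                    stringsAsFactors = FALSE)
  }
  out
}

#' Run the full pipeline on simulated data
#'
#' Simulates a host/EVE pair, integrates, resolves and classifies the
#' junction, extracts and profiles the attachment sites, simulates long
#' reads from the configured molecule classes and detects the excision
#' signatures, then simulates the meiotic cross and tests linkage.
#' Deterministic given the config seed.
#'
#' @param config a `RunConfig` from [default_config()] or
#'   [read_config()].
#' @param out_dir optional directory; when given, FASTA/FASTQ/BED/TSV/
#'   JSON outputs are written there.
#' @return list with `junctions` (classified `junction_record`),
#'   `quartet` (`att_quartet`), `excision` (`excision_report`),
#'   `linkage` (`linkage_result`), `progeny`, and `truth`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  sim <- config$simulate

  host <- make_host_genome(1, sim$host_length, sim$host_gc, seed = seed)
  site <- as.integer(sim$site_fraction * sim$host_length)
  host[1] <- plant_attB(host[[1]], site)
  espec <- eve_spec(length_bp = sim$eve_length, gc_fraction = sim$eve_gc,
                    seed = seed + 1L)
  eve <- make_eve(espec)
  integ <- integrate_eve(host[1], eve$seq, site, espec$attP_core,
                         eve_truth = eve$truth)

  k <- config$junctions$k
  recs <- resolve_insertion(integ$seq, host[1], k = k)
  eseq <- eve$seq[[1]]
  recs <- classify_mechanism(recs[1, ], integ$seq, host[1],
                             eve_left_end = substr(eseq, 1, 200),
                             eve_right_end = substr(eseq,
                                                    nchar(eseq) - 199,
                                                    nchar(eseq)))
  quartet <- extract_att_quartet(recs, integ$seq, host[1],
                                 flank_w = config$junctions$flank_w)

  exc <- excise_to_circle(integ$seq, integ$truth)
  hairpins <- make_hairpin_templates(exc$circle, espec$telrl)
  depths <- unlist(config$simulate$depths)
  if (!isTRUE(sim$symptomatic))
    depths <- depths[c("integrated", "host_background")]
  rspec <- read_sim_spec(depths, read_length = sim$read_length,
                         error_rate = sim$error_rate, seed = seed + 2L)
  templates <- list(integrated = integ$seq, circle = exc$circle,
                    hairpin = hairpins, host_background = exc$restored_host)
  reads <- simulate_reads(templates, rspec)

  ei <- integ$truth[integ$truth$feature == "EVE_interval", ]
  eve_interval <- c(ei$start[1], ei$end[1])
  excfg <- config$excision
  anchors <- read_anchors(reads, integ$seq, k)
  span <- detect_attP_spanning(reads, integ$seq, eve_interval, k = k,
                               anchors = anchors)
  fb <- detect_foldback(reads, integ$seq, min_arm = excfg$min_arm, k = k,
                        anchors = anchors)
  telsite <- NULL
  if (nrow(fb) >= 1) {
    clus <- cluster_reversions(fb)
    telsite <- locate_telrl(clus$consensus_coord, integ$seq,
                            window = excfg$telrl_window,
                            core_min = excfg$core_min,
                            core_max = excfg$core_max)
  }
  cov <- coverage_ratio(reads, integ$seq, eve_interval, k = k,
                        anchors = anchors)
  report <- summarize_excision(span, fb, telsite, cov,
                               min_span = excfg$min_span,
                               min_fb = excfg$min_fb,
                               min_ratio = excfg$min_ratio)

  cr <- config$cross
  cspec <- cross_spec(cr$loci, cr$active, cr$penetrance, cr$n_progeny,
                      seed = seed + 3L)
  progeny <- simulate_cross(cspec)
  linkage <- linkage_test(locus_phenotype_table(progeny, cr$active[1]))

  result <- list(junctions = recs, quartet = quartet, excision = report,
                 linkage = linkage, progeny = progeny,
                 truth = integ$truth, reads = reads,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, integ, out_dir)
  result
}

write_pipeline_outputs <- function(result, integ, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(integ$seq, file.path(out_dir, "bearing.fasta"))
  write_fastq(result$reads, file.path(out_dir, "reads.fastq"))
  write_bed(truth_to_features(result$truth),
            file.path(out_dir, "truth.bed"))
  write.table(as.data.frame(result$junctions),
              file.path(out_dir, "junctions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(c(attB = result$quartet$attB, attP = result$quartet$attP,
                attL = result$quartet$attL, attR = result$quartet$attR),
              file.path(out_dir, "att_sites.fasta"))
  write_progeny_table(result$progeny, file.path(out_dir, "progeny.tsv"))
  rep <- result$excision
  jsonlite::write_json(
    list(n_span = rep$n_span, n_foldback = rep$n_foldback,
         telrl_coord = rep$telrl_coord, palindrome_len = rep$palindrome_len,
         coverage_ratio = rep$coverage_ratio, flags = rep$flags,
         linkage_chi2 = unname(result$linkage$statistic),
         linkage_p = result$linkage$p.value,
         seed = result$config$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
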