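## Synthetic-data generators: host genomes, EVEs with the terminal
## architecture of phaeoviral insertions, integration/excision products,
## hairpin-telomere templates, long reads, and segregating meiotic progeny.
## Every generator is a pure function of its seed.

#' Specification of a telomere-resolution (telRL) site
#'
#' The telRL site of a circular phaeoviral genome is a short palindromic
#' core inside a larger inverted repeat; telomere resolvase cleaves with a
#' staggered cut at the core and reseals the ends as covalently closed
#' hairpin telomeres (telL/telR).
#'
#' @param core_palindrome even-length DNA string equal to its own reverse
#'   complement (default `"TTCGAA"`, 6 bp).
#' @param outer_ir_arm length in bp of the perfect inverted-repeat arms
#'   placed around the core (default 15).
#' @param position_fraction position of the core as a fraction of EVE
#'   length (default 0.5).
#' @param stagger_nt length of the staggered cut, i.e. the hairpin apex
#'   loop (default 6).
#' @return a list of class `telrl_spec`.
#' @export
telrl_spec <- function(core_palindrome = "TTCGAA", outer_ir_arm = 15L,
                       position_fraction = 0.5, stagger_nt = 6L) {
  if (!is_palindrome(core_palindrome))
    stop_input("core_palindrome must be a non-empty even-length palindrome ",
               "(equal to its own reverse complement)")
  if (stagger_nt < 0) stop_input("stagger_nt must be >= 0")
  if (position_fraction <= 0 || position_fraction >= 1)
    stop_input("position_fraction must be in (0, 1)")
  structure(list(core_palindrome = core_palindrome,
                 outer_ir_arm = as.integer(outer_ir_arm),
                 position_fraction = position_fraction,
                 stagger_nt = as.integer(stagger_nt)),
            class = "telrl_spec")
}

#' Specification of an IS4-family transposon
#'
#' @param length_bp element length (default 2000).
#' @param tsd_len target-site-duplication length generated on insertion
#'   (default 8, the IS4-family signature).
#' @return a list of class `is4_spec`.
#' @export
is4_spec <- function(length_bp = 2000L, tsd_len = 8L) {
  if (tsd_len < 0) stop_input("tsd_len must be >= 0")
  if (length_bp < 10) stop_input("length_bp must be >= 10")
  structure(list(length_bp = as.integer(length_bp),
                 tsd_len = as.integer(tsd_len)),
            class = "is4_spec")
}

#' Specification of a synthetic EVE
#'
#' Describes a scaled-down endogenous viral element with the terminal
#' architecture observed in integrated phaeoviruses: an attP core
#' dinucleotide flanked by AT-rich inverted-repeat arms, a conserved
#' inverted repeat near the left terminus, imperfect direct repeats near
#' the right terminus, and an internal palindromic telRL site. Real
#' elements are 288-407 kb; the default 30 kb keeps desk-scale runtimes
#' while preserving every junction-level feature.
#'
#' @param length_bp total EVE length including one attP core copy
#'   (default 30000).
#' @param gc_fraction background GC (default 0.52, the observed EVE
#'   composition).
#' @param attP_core the recombination core (default `"CC"`).
#' @param flank_ir list with `arm_len` and `at_fraction` for the AT-rich
#'   arms flanking the core in the circular attP site.
#' @param left_end_ir list with `arm_len`, `loop_len`, `offset` for the
#'   conserved inverted repeat near the left terminus.
#' @param right_end_direct list with `unit_len`, `mismatches`,
#'   `offset_from_end` for the imperfect direct repeats near the right
#'   terminus.
#' @param telrl a [telrl_spec()].
#' @param transposon optional [is4_spec()]; when present one element copy
#'   is inserted between the telRL site and the right terminus, with its
#'   target site duplicated.
#' @param seed integer RNG seed.
#' @return a list of class `eve_spec`.
#' @export
eve_spec <- function(length_bp = 30000L, gc_fraction = 0.52,
                     attP_core = "CC",
                     flank_ir = list(arm_len = 12L, at_fraction = 0.8),
                     left_end_ir = list(arm_len = 10L, loop_len = 8L,
                                        offset = 40L),
                     right_end_direct = list(unit_len = 15L, mismatches = 1L,
                                             offset_from_end = 60L),
                     telrl = telrl_spec(), transposon = NULL, seed = 1L) {
  if (!nzchar(attP_core)) stop_input("attP_core must be non-empty")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop_input("gc_fraction must be in (0, 1)")
  if (!inherits(telrl, "telrl_spec")) stop_input("telrl must be a telrl_spec")
  if (!is.null(transposon) && !inherits(transposon, "is4_spec"))
    stop_input("transposon must be NULL or an is4_spec")
  structure(list(length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction, attP_core = attP_core,
                 flank_ir = flank_ir, left_end_ir = left_end_ir,
                 right_end_direct = right_end_direct, telrl = telrl,
                 transposon = transposon, seed = as.integer(seed)),
            class = "eve_spec")
}

## The attB context planted in host genomes: weak 'ATA' contribution
## followed by the near-invariant 'CC' core.
ATT_B_MOTIF <- "ATACC"

#' Generate random host chromosomes
#'
#' Emits uniform-composition chromosomes at the requested GC and
#' guarantees at least one attB motif context (`"ATACC"`) per 10 kb,
#' planting one mid-block where none arose by chance.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector of lengths (recycled to `n_chrom`).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return named character vector of DNA strings (`chr01`, `chr02`, ...).
#' @export
make_host_genome <- function(n_chrom, lengths, gc = 0.5, seed = 1L) {
  if (any(lengths <= 0)) stop_input("chromosome lengths must be positive")
  if (gc <= 0 || gc >= 1) stop_input("gc must be in (0, 1)")
  lengths <- rep_len(as.integer(lengths), n_chrom)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      s <- random_dna(lengths[i], gc)
      blocks <- seq(0L, max(lengths[i] - 1L, 0L), by = 10000L)
      for (b in blocks) {
        bend <- min(b + 10000L, lengths[i])
        if (bend - b < nchar(ATT_B_MOTIF) + 2L) next
        win <- subseq0(s, b, bend)
        if (!grepl(ATT_B_MOTIF, win, fixed = TRUE)) {
          mid <- b + (bend - b) %/% 2L
          s <- splice_in(s, mid, ATT_B_MOTIF)
        }
      }
      s
    }, character(1))
    names(seqs) <- sprintf("chr%02d", seq_len(n_chrom))
    seqs
  })
}

#' Plant an attB site in a host chromosome
#'
#' Writes the `ATACC` attB context so that the `CC` core ends at `site`,
#' and sets the following base to `A` so that integration of a
#' default-architecture EVE produces exactly 2 bp of junction
#' microhomology (no accidental extension on either side).
#'
#' @param host single DNA string.
#' @param site 0-based coordinate where the core's right edge will lie.
#' @return modified host string.
#' @export
plant_attB <- function(host, site) {
  m <- nchar(ATT_B_MOTIF)
  if (site < m || site >= nchar(host))
    stop_input("site leaves no room for the attB motif")
  splice_in(host, as.integer(site) - m, paste0(ATT_B_MOTIF, "A"))
}

## Assemble the telRL block: outer IR arm + spacer + core + spacer + rc(arm).
## The 'ACG' spacers block palindrome extension beyond the core (the base
## right of the core, 'A', is not the complement of the base left of it,
## 'G'), so the core is the maximal even palindrome at its center while the
## outer arms still form a larger inverted repeat around it.
telrl_block <- function(ts, gc) {
  arm <- random_dna(ts$outer_ir_arm, gc)
  sp <- "ACG"
  list(block = paste0(arm, sp, ts$core_palindrome, sp, revcomp(arm)),
       core_offset = ts$outer_ir_arm + nchar(sp), spacer = sp, arm = arm)
}

#' Generate a synthetic EVE with ground truth
#'
#' Emits the element in its integrated orientation: the left terminus
#' (the AT-rich attP-flank arm followed by the conserved left-end
#' inverted repeat) begins the sequence, the right terminus (imperfect
#' direct repeats, the partner AT-rich arm) ends it, and the single attP
#' core copy is the final bases — the copy that the virus contributes to
#' the right junction on integration. The telRL core is placed at
#' `floor(position_fraction * length)`.
#'
#' @param spec an [eve_spec()].
#' @param id sequence identifier (default `"EVE1"`).
#' @return list with `seq` (named DNA string) and `truth` (data frame of
#'   0-based half-open feature records).
#' @export
make_eve <- function(spec, id = "EVE1") {
  stopifnot(inherits(spec, "eve_spec"))
  N <- spec$length_bp
  cl <- nchar(spec$attP_core)
  fa <- as.integer(spec$flank_ir$arm_len)
  ts <- spec$telrl
  with_seed(spec$seed, {
    ## AT-rich attP-flank arms with guaranteed composition; armA's last
    ## base is fixed to 'C' so the junction microhomology never extends
    ## left of the core, and armB (its reverse complement) therefore
    ## starts with 'G'.
    n_at <- min(fa - 1L,
                max(round(spec$flank_ir$at_fraction * fa),
                    ceiling(0.7 * fa)))
    bases <- c(sample(c("A", "T"), n_at, replace = TRUE),
               sample(c("C", "G"), fa - 1L - n_at, replace = TRUE))
    armA <- paste(c(sample(bases), "C"), collapse = "")
    armB <- revcomp(armA)

    le <- spec$left_end_ir
    le_arm <- random_dna(le$arm_len, spec$gc_fraction)
    le_loop <- random_dna(le$loop_len, spec$gc_fraction)
    le_block <- paste0(le_arm, le_loop, revcomp(le_arm))
    le_start <- as.integer(le$offset)

    tb <- telrl_block(ts, spec$gc_fraction)
    tp <- as.integer(floor(ts$position_fraction * N))
    tb_start <- tp - tb$core_offset
    tb_end <- tb_start + nchar(tb$block)

    rd <- spec$right_end_direct
    unit <- random_dna(rd$unit_len, spec$gc_fraction)
    unit2 <- unit
    if (rd$mismatches > 0) {
      pos <- sample(seq_len(rd$unit_len), rd$mismatches)
      for (p in pos) {
        b <- substr(unit2, p, p)
        substr(unit2, p, p) <- sample(setdiff(DNA_BASES, b), 1)
      }
    }
    rd_block <- paste0(unit, unit2)
    rd_start <- N - cl - fa - as.integer(rd$offset_from_end)
    rd_end <- rd_start + nchar(rd_block)

    if (le_start < fa || le_start + nchar(le_block) >= tb_start ||
        tb_end >= rd_start || rd_end > N - cl - fa)
      stop_input("telRL position collides with terminal feature blocks; ",
                 "increase length_bp or move position_fraction")

    s <- random_dna(N, spec$gc_fraction)
    s <- splice_in(s, 0L, armB)
    s <- splice_in(s, le_start, le_block)
    s <- splice_in(s, tb_start, tb$block)
    s <- splice_in(s, rd_start, rd_block)
    s <- splice_in(s, N - cl - fa, armA)
    s <- splice_in(s, N - cl, spec$attP_core)
    ## guard: the base just before the right direct repeats must not
    ## recreate complementarity that would extend the telRL palindrome;
    ## nothing to do — spacers inside the block already block extension.

    truth <- rbind(
      truth_df(id, "flank_ir_left_arm", 0L, fa, armB),
      truth_df(id, "left_end_ir", le_start, le_start + nchar(le_block),
               sprintf("arm=%d;loop=%d", le$arm_len, le$loop_len)),
      truth_df(id, "telRL", tp, tp + nchar(ts$core_palindrome),
               ts$core_palindrome),
      truth_df(id, "telRL_outer_ir", tb_start, tb_end,
               sprintf("arm=%d", ts$outer_ir_arm)),
      truth_df(id, "right_end_direct", rd_start, rd_end,
               sprintf("unit=%d;mismatches=%d", rd$unit_len, rd$mismatches)),
      truth_df(id, "flank_ir_right_arm", N - cl - fa, N - cl, armA),
      truth_df(id, "attP_core", N - cl, N, spec$attP_core)
    )

    if (!is.null(spec$transposon)) {
      tsd <- insert_is4(s, spec$transposon,
                        lo = tb_end + 200L, hi = rd_start - 200L)
      delta <- nchar(tsd$seq) - N
      shift <- truth$start >= tsd$mp
      truth$start[shift] <- truth$start[shift] + delta
      truth$end[shift] <- truth$end[shift] + delta
      s <- tsd$seq
      truth <- rbind(truth, tsd$truth_rows(id))
    }

    list(seq = setNames(s, id), truth = truth)
  })
}

## Insert an IS4 element with target-site duplication into `s`, at a
## position within [lo, hi). Terminal element bases are adjusted so the
## duplication never extends by chance, keeping tsd_len exact.
insert_is4 <- function(s, is4, lo, hi) {
  t <- is4$tsd_len
  if (hi - lo < t + 2L)
    stop_input("no room for the transposon between telRL and right terminus")
  mp <- lo + (hi - lo) %/% 2L
  target <- subseq0(s, mp, mp + t)
  E <- random_dna(is4$length_bp, 0.45)
  after <- substr(s, mp + t + 1L, mp + t + 1L)
  before <- substr(s, mp, mp)       # base at mp-1 in 0-based terms
  E <- paste0(sample(setdiff(DNA_BASES, after), 1),
              substr(E, 2, is4$length_bp - 1L),
              sample(setdiff(DNA_BASES, before), 1))
  new_s <- paste0(subseq0(s, 0L, mp + t), E, subseq0(s, mp, nchar(s)))
  eL <- mp + t + nchar(E)
  list(seq = new_s, mp = mp,
       truth_rows = function(id) rbind(
         truth_df(id, "TSD", mp, mp + t, paste0("left;", target)),
         truth_df(id, "IS4", mp + t, eL, sprintf("len=%d", nchar(E))),
         truth_df(id, "TSD", eL, eL + t, paste0("right;", target))
       ))
}

#' Integrate an EVE into a host chromosome
#'
#' Models tyrosine-recombinase integration across a shared core: the host
#' contributes the core copy at the left junction and the virus the copy
#' at the right junction, with no duplication beyond the shared core. The
#' integrated haplotype is `host[0..site) + eve + host[site..)` where the
#' host core occupies `[site - |core|, site)` and the EVE ends with its
#' own core copy.
#'
#' @param host named DNA string (single chromosome).
#' @param eve named DNA string from [make_eve()] (integrated orientation,
#'   trailing core).
#' @param site 0-based host coordinate of the core's right edge.
#' @param core the recombination core (default `"CC"`).
#' @param eve_truth optional truth data frame from [make_eve()]; its
#'   records are lifted onto the integrated haplotype.
#' @return list with `seq` (the EVE-bearing haplotype) and `truth`
#'   (attL/attR/attB/EVE_interval records plus lifted EVE features). The
#'   EVE_interval is reported in the leftmost-canonical convention.
#' @export
integrate_eve <- function(host, eve, site, core = "CC", eve_truth = NULL) {
  site <- as.integer(site)
  cl <- nchar(core)
  hseq <- unname(host[1]); eseq <- unname(eve[1])
  hid <- names(host)[1] %||% "host"; eid <- names(eve)[1] %||% "eve"
  if (site < cl || site > nchar(hseq))
    stop_input("site out of range for host")
  if (subseq0(hseq, site - cl, site) != core)
    stop_input("host does not carry core '", core, "' ending at site ", site)
  if (subseq0(eseq, nchar(eseq) - cl, nchar(eseq)) != core)
    stop_input("EVE does not end with core '", core, "'")
  N <- nchar(eseq)
  bearing <- insert_at(hseq, site, eseq)
  bid <- paste0(hid, "+", eid)
  truth <- rbind(
    truth_df(bid, "EVE_interval", site - cl, site + N - cl,
             "leftmost-canonical"),
    truth_df(bid, "attL", site - cl, site, core),
    truth_df(bid, "attR", site + N - cl, site + N, core),
    truth_df(hid, "attB", site - cl, site, core)
  )
  if (!is.null(eve_truth)) {
    lifted <- eve_truth
    lifted$genome_id <- bid
    lifted$start <- lifted$start + site
    lifted$end <- lifted$end + site
    truth <- rbind(truth, lifted)
  }
  list(seq = setNames(bearing, bid), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Excise an integrated EVE into its circular form
#'
#' Reverses [integrate_eve()]: recombination between attL and attR
#' restores the pre-integration host exactly and releases a circle
#' carrying a single core copy. The circle is returned as a linear string
#' whose origin is the attP core start.
#'
#' @param integrated named DNA string (the EVE-bearing haplotype).
#' @param truth truth data frame containing the `EVE_interval` record for
#'   this genome.
#' @return list with `circle`, `restored_host`, and `truth` (EVE-internal
#'   features remapped onto circle coordinates).
#' @export
excise_to_circle <- function(integrated, truth) {
  bid <- names(integrated)[1] %||% "bearing"
  rec <- truth[truth$genome_id == bid & truth$feature == "EVE_interval", ]
  if (nrow(rec) == 0)
    stop_input("truth has no EVE_interval record for '", bid, "'")
  s <- rec$start[1]; e <- rec$end[1]
  bseq <- unname(integrated[1])
  circle <- subseq0(bseq, s, e)
  restored <- paste0(subseq0(bseq, 0L, s), subseq0(bseq, e, nchar(bseq)))
  int_truth <- truth[truth$genome_id == bid & truth$start >= s &
                       truth$end <= e &
                       !truth$feature %in% c("EVE_interval", "attL", "attR"), ]
  if (nrow(int_truth) > 0) {
    int_truth$genome_id <- "circle"
    int_truth$start <- int_truth$start - s
    int_truth$end <- int_truth$end - s
  }
  list(circle = c(circle = circle),
       restored_host = setNames(restored, sub("\\+.*$", "", bid)),
       truth = int_truth)
}

#' Build hairpin-telomere read templates from a circular genome
#'
#' Telomere resolvase cleaves the telRL site with a staggered cut and
#' reseals each end as a covalently closed hairpin. A sequencing read
#' crossing such an end traverses one arm, the apex loop, and the reverse
#' complement of the arm. Two linear templates are returned, one per end
#' (telL: the side left of the apex; telR: the side right of it). The
#' apex loop is the central `stagger_nt` bases of the core's top strand.
#'
#' @param circle named DNA string with origin at the attP core.
#' @param telrl a [telrl_spec()]; its core is located as the occurrence
#'   nearest `position_fraction * length(circle)`.
#' @param arm_len arm length carried into each template (default 2000).
#' @return named character vector `c(telL=, telR=)` with attribute
#'   `apex_center` (0-based boundary coordinate of the apex midpoint on
#'   the circle) and `apex_interval`.
#' @export
make_hairpin_templates <- function(circle, telrl, arm_len = 2000L) {
  s <- unname(circle[1])
  core <- telrl$core_palindrome
  k <- nchar(core)
  occ <- gregexpr(core, s, fixed = TRUE)[[1]]
  if (occ[1] == -1) stop_input("telRL core not found in circle")
  p <- as.integer(occ) - 1L
  want <- telrl$position_fraction * nchar(s)
  p <- p[which.min(abs(p - want))]
  st <- telrl$stagger_nt
  a0 <- p + (k - st) %/% 2L
  apex <- subseq0(s, a0, a0 + st)
  arm_len <- as.integer(arm_len)
  XL <- subseq0(s, max(0L, a0 - arm_len), a0)
  R <- subseq0(s, a0 + st, min(nchar(s), a0 + st + arm_len))
  tl <- paste0(XL, apex, revcomp(XL))
  tr <- paste0(revcomp(R), apex, R)
  out <- c(telL = tl, telR = tr)
  attr(out, "apex_center") <- a0 + st %/% 2L
  attr(out, "apex_interval") <- c(a0, a0 + st)
  out
}

#' Specification for long-read simulation
#'
#' @param depth_per_class named numeric vector of mean depths for the
#'   molecule classes (`integrated`, `circle`, `hairpin`,
#'   `host_background`); only classes present are simulated.
#' @param read_length numeric `(mean, sd)` in bp.
#' @param error_rate per-base substitution probability in \[0, 0.2\].
#' @param seed integer RNG seed.
#' @return a list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth_per_class, read_length = c(1200, 200),
                          error_rate = 0, seed = 1L) {
  if (any(depth_per_class < 0)) stop_input("depths must be >= 0")
  if (error_rate < 0 || error_rate > 0.2)
    stop_input("error_rate must be in [0, 0.2]")
  structure(list(depth_per_class = depth_per_class,
                 read_length = read_length, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

## Per-base substitution errors.
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(v, collapse = "")
}

#' Simulate long reads from molecule-class templates
#'
#' Reads are sampled uniformly along each template; for the `circle`
#' class the start position wraps around the origin. Read names encode
#' `class|template|start|length|index` so truth-aware tests can recover
#' the source. Reads are emitted on the forward strand of their template
#' (the downstream detectors scan both strands).
#'
#' @param templates named list mapping class name to a named character
#'   vector of template sequences.
#' @param spec a [read_sim_spec()].
#' @return named character vector of reads.
#' @export
simulate_reads <- function(templates, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  with_seed(spec$seed, {
    out <- character(0)
    for (cls in names(spec$depth_per_class)) {
      depth <- spec$depth_per_class[[cls]]
      if (depth <= 0) next
      tpl <- templates[[cls]]
      if (is.null(tpl) || length(tpl) == 0)
        stop_input("positive depth for class '", cls, "' but no template")
      for (ti in seq_along(tpl)) {
        tname <- names(tpl)[ti] %||% as.character(ti)
        s <- unname(tpl[ti])
        len <- nchar(s)
        mu <- spec$read_length[1]
        n_reads <- rpois(1, depth * len / mu)
        if (n_reads == 0) next
        rl <- pmax(50L, pmin(len, as.integer(round(
          rnorm(n_reads, mu, spec$read_length[2])))))
        circular <- identical(cls, "circle")
        src <- if (circular) paste0(s, s) else s
        starts <- if (circular) {
          as.integer(floor(runif(n_reads, 0, len)))
        } else {
          as.integer(floor(runif(n_reads, 0, len - rl + 1)))
        }
        reads <- substring(src, starts + 1L, starts + rl)
        if (spec$error_rate > 0)
          reads <- vapply(reads, mutate_seq, "", rate = spec$error_rate,
                          USE.NAMES = FALSE)
        names(reads) <- sprintf("%s|%s|%d|%d|%d", cls, tname, starts, rl,
                                seq_len(n_reads))
        out <- c(out, reads)
      }
    }
    out
  })
}

#' Specification of a meiotic cross
#'
#' Loci are hemizygous EVE insertions; each chromosome transmits one of
#' its two homologues with probability 1/2 independently, so unlinked
#' loci segregate 1:1 and two loci on different homologues of the same
#' chromosome are mutually exclusive (exactly one inherited).
#'
#' @param loci data frame with columns `locus_id`, `chromosome_id`,
#'   `homolog` (0 or 1).
#' @param active_loci character vector of loci whose presence causes
#'   viral symptoms.
#' @param penetrance probability that a carrier expresses symptoms
#'   (default 1).
#' @param n_progeny number of haploid progeny.
#' @param seed integer RNG seed.
#' @return a list of class `cross_spec`.
#' @export
cross_spec <- function(loci, active_loci, penetrance = 1, n_progeny, seed = 1L) {
  stopifnot(is.data.frame(loci),
            all(c("locus_id", "chromosome_id", "homolog") %in% names(loci)))
  if (!all(active_loci %in% loci$locus_id))
    stop_input("active locus not among declared loci")
  if (penetrance < 0 || penetrance > 1)
    stop_input("penetrance must be in [0, 1]")
  if (!all(loci$homolog %in% c(0L, 1L)))
    stop_input("homolog must be 0 or 1")
  structure(list(loci = loci, active_loci = active_loci,
                 penetrance = penetrance, n_progeny = as.integer(n_progeny),
                 seed = as.integer(seed)),
            class = "cross_spec")
}

#' Simulate a segregating meiotic progeny
#'
#' @param spec a [cross_spec()].
#' @return a data frame of class `progeny_table`: `individual_id`, one
#'   logical column per locus (presence), and `phenotype`
#'   (`"symptomatic"`/`"asymptomatic"`). Attributes `loci` and
#'   `active_loci` carry the design.
#' @export
simulate_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  loci <- spec$loci
  n <- spec$n_progeny
  with_seed(spec$seed, {
    chroms <- unique(loci$chromosome_id)
    inherit <- matrix(rbinom(n * length(chroms), 1L, 0.5), nrow = n,
                      dimnames = list(NULL, chroms))
    geno <- sapply(seq_len(nrow(loci)), function(i) {
      inherit[, loci$chromosome_id[i]] == loci$homolog[i]
    })
    geno <- matrix(geno, nrow = n,
                   dimnames = list(NULL, loci$locus_id))
    carrier <- if (length(spec$active_loci) > 0) {
      rowSums(geno[, spec$active_loci, drop = FALSE]) > 0
    } else rep(FALSE, n)
    expressed <- carrier & (runif(n) < spec$penetrance)
    tab <- data.frame(individual_id = sprintf("ind%04d", seq_len(n)),
                      geno,
                      phenotype = ifelse(expressed, "symptomatic",
                                         "asymptomatic"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    attr(tab, "loci") <- loci
    attr(tab, "active_loci") <- spec$active_loci
    class(tab) <- c("progeny_table", "data.frame")
    tab
  })
}
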