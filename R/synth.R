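#' Configuration of a synthetic cohort
#'
#' Defines the generative conditions of a labelled synthetic cohort:
#' consanguineous individuals whose autozygous segments arise from pedigree
#' recombination, de novo mutations planted at rate `mu` per bp per
#' generation over the autozygous genome, non-crossover gene conversions
#' copying segregating alleles in proportion to their population frequency,
#' segment-boundary over-call contamination, false-positive het calls, and
#' frequency-resolved false-negative dropout.
#'
#' Defaults mirror the study conditions the estimators target: a mutation
#' rate of 1.45e-8 and conversion rate of 8.75e-6 per bp per generation, a
#' 1 percent false-positive rate, false-negative rates of 17 percent for
#' singletons and 7.9 percent above 10 percent MAF, population
#' heterozygosity 9.56e-4 per bp, mean depth 27x, and a relationship mix
#' (30/35/25/10 percent first to fourth cousins) whose length-weighted mean
#' separating meioses is ~6.6, between first- and second-cousin parentage.
#'
#' @param n_individuals cohort size.
#' @param relationship_mix named fractions over
#'   `first_cousin`..`fourth_cousin`, summing to 1.
#' @param genome a [genome_model()]; default [scaled_genome()] (4 x 150 Mb),
#'   which preserves human segment-length statistics at desk scale.
#' @param mu de novo mutation rate per bp per generation.
#' @param conversion_rate non-crossover gene-conversion rate per bp per
#'   generation.
#' @param alpha false-positive het-call rate (fraction of emitted calls).
#' @param fn_singleton,fn_low,fn_common false-negative rates for singletons,
#'   rare variants (MAF below 10 percent) and common variants.
#' @param target_het population heterozygosity per bp to calibrate the
#'   number of segregating sites.
#' @param depth_mean mean sequencing depth (used by duplicate/spike-in
#'   helpers).
#' @param edge_overshoot_bp mean (exponential) over-run of observed segment
#'   boundaries beyond the true IBD segment.
#' @param edge_hets_per_end expected population heterozygotes contaminating
#'   each over-called boundary zone.
#' @param seed optional seed recorded in the config and set by
#'   [generate_cohort()].
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_individuals = 500,
                          relationship_mix = c(first_cousin = 0.30,
                                               second_cousin = 0.35,
                                               third_cousin = 0.25,
                                               fourth_cousin = 0.10),
                          genome = scaled_genome(),
                          mu = 1.45e-8,
                          conversion_rate = 8.75e-6,
                          alpha = 0.01,
                          fn_singleton = 0.17,
                          fn_low = 0.12,
                          fn_common = 0.079,
                          target_het = 9.56e-4,
                          depth_mean = 27,
                          edge_overshoot_bp = 1e5,
                          edge_hets_per_end = 1.5,
                          seed = NULL) {
  if (abs(sum(relationship_mix) - 1) > 1e-8)
    stop("'relationship_mix' must sum to 1")
  probs <- c(mu, conversion_rate, alpha, fn_singleton, fn_low, fn_common)
  if (any(probs < 0) || any(probs >= 1))
    stop("rates must lie in [0, 1)")
  structure(as.list(environment()), class = "cohort_config")
}

# FN table matching the config bands for a cohort of allele number AN.
.config_fn_table <- function(config, an) {
  fn_table(lo = c(0, 1.5 / an, 0.10),
           hi = c(1.5 / an, 0.10, 0.50),
           beta = c(config$fn_singleton, config$fn_low, config$fn_common))
}

# Draw `n` alternate-allele counts from a neutral (1/k) frequency spectrum.
.neutral_ac <- function(n, an) {
  k <- seq_len(an - 1)
  sample.int(an - 1, n, replace = TRUE, prob = 1 / k)
}

# random ref/alt base pairs, transitions twice as likely as transversions
.rand_substitution <- function(n) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  alt <- ifelse(stats::runif(n) < 2 / 3, transition[ref],
                ifelse(stats::runif(n) < 0.5,
                       c(A = "C", C = "A", G = "C", T = "A")[ref],
                       c(A = "T", C = "G", G = "T", T = "G")[ref]))
  data.frame(ref = ref, alt = unname(alt))
}

#' Generate a fully labelled synthetic cohort
#'
#' Draws each individual's relationship from the configured mix, simulates
#' its true autozygous segments by pedigree gene-dropping, over-calls segment
#' boundaries by an exponential overshoot (with population heterozygotes
#' contaminating the over-called zones, emulating segment-caller over-run),
#' plants de novo mutations uniformly over the true autozygous genome at
#' rate `mu * M` per bp, plants gene conversions on segregating sites with
#' probability proportional to site heterozygosity at rate
#' `c * M * 2p(1-p)` per site, thins all true heterozygotes by the
#' frequency-band false-negative rates, and adds false-positive singleton
#' calls so that a fraction `alpha` of emitted calls is spurious in
#' expectation. Every emitted call traces to exactly one truth-ledger entry.
#'
#' @param config a [cohort_config()].
#' @return List of class `"az_cohort"`:
#'   `calls` ([het_calls()]), `segments` (observed [segment_set()]),
#'   `true_segments`, `sfs` ([sfs_summary()] of the segregating-site panel),
#'   `fn_table`, `ledger` (list `individuals`, `events`), `genome`, `an`,
#'   and the `config`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_individuals = 50, seed = 1)
#' coh <- generate_cohort(cfg)
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- config$genome
  n <- config$n_individuals
  an <- 2L * n
  fn_tab <- .config_fn_table(config, an)
  ids <- sprintf("ind%04d", seq_len(n))
  rels <- sample(names(config$relationship_mix), n, replace = TRUE,
                 prob = config$relationship_mix)
  peds <- lapply(stats::setNames(nm = unique(rels)), build_pedigree)
  meioses <- vapply(rels, function(r) peds[[r]]$meioses, integer(1))

  ## segregating-site panel calibrated to the target heterozygosity
  total_bp <- sum(genome$length_bp)
  k <- seq_len(an - 1)
  wk <- (1 / k) / sum(1 / k)
  e2pq <- sum(wk * 2 * (k / an) * (1 - k / an))
  s_sites <- max(1L, round(config$target_het * total_bp / e2pq))
  site_chrom <- sample.int(length(genome$chrom), s_sites, replace = TRUE,
                           prob = genome$length_bp)
  site_pos <- floor(stats::runif(s_sites) *
                      genome$length_bp[site_chrom]) + 1
  site_ac <- .neutral_ac(s_sites, an)
  o <- order(site_chrom, site_pos)
  site_chrom <- site_chrom[o]; site_pos <- site_pos[o]; site_ac <- site_ac[o]
  site_p <- site_ac / an
  site_hetw <- 2 * site_p * (1 - site_p)
  # per-chromosome offsets and cumulative het mass for O(1) range sums
  chrom_first <- findInterval(seq_along(genome$chrom) - 0.5, site_chrom) + 1L
  chrom_last <- findInterval(seq_along(genome$chrom) + 0.5, site_chrom)
  pos_by_chrom <- split(site_pos, factor(site_chrom,
                                         levels = seq_along(genome$chrom)))
  cumw <- cumsum(site_hetw)
  range_sum <- function(lo, hi)  # inclusive index range, 0 when empty
    if (hi < lo) 0 else cumw[hi] - if (lo > 1) cumw[lo - 1] else 0
  # MAF pool for boundary-contamination heterozygotes (het-mass weighted)
  pool_idx <- sample.int(s_sites, 20000, replace = TRUE, prob = site_hetw)

  true_segs <- vector("list", n)
  obs_segs <- vector("list", n)
  events <- vector("list", n)
  chrom_names <- genome$chrom
  chrom_index <- stats::setNames(seq_along(chrom_names), chrom_names)
  pool_at <- 0L
  take_pool <- function(m) {
    if (pool_at + m > length(pool_idx))
      stop("boundary-contamination pool exhausted")  # pool sized generously
    out <- pool_idx[pool_at + seq_len(m)]; pool_at <<- pool_at + m; out
  }

  for (i in seq_len(n)) {
    segs <- simulate_autozygosity(peds[[rels[i]]], genome, ids[i])
    true_segs[[i]] <- segs
    m_i <- meioses[i]
    ev <- list()
    if (nrow(segs)) {
      ci <- chrom_index[segs$chrom]
      len <- segs$end - segs$start
      l_i <- sum(len)
      ## observed segments: exponential boundary over-run at each end
      ext_l <- stats::rexp(nrow(segs), 1 / config$edge_overshoot_bp)
      ext_r <- stats::rexp(nrow(segs), 1 / config$edge_overshoot_bp)
      if (config$edge_overshoot_bp == 0) ext_l[] <- ext_r[] <- 0
      ostart <- pmax(0, segs$start - ext_l)
      oend <- pmin(genome$length_bp[ci], segs$end + ext_r)
      # merge any overlap created by extension
      om <- data.frame(chrom = segs$chrom, start = ostart, end = oend)
      om <- om[order(ci, om$start), , drop = FALSE]
      merged <- list(); last <- NULL
      for (r in seq_len(nrow(om))) {
        if (!is.null(last) && om$chrom[r] == last$chrom &&
            om$start[r] <= last$end) {
          last$end <- max(last$end, om$end[r])
        } else {
          if (!is.null(last)) merged[[length(merged) + 1L]] <- last
          last <- om[r, ]
        }
      }
      merged[[length(merged) + 1L]] <- last
      om <- do.call(rbind, merged)
      obs_segs[[i]] <- segment_set(om$chrom, om$start, om$end, ids[i],
                                   annotation = "observed")

      ## de novo mutations, uniform over the true autozygous genome
      n_dnm <- stats::rpois(1, config$mu * l_i * m_i)
      if (n_dnm > 0) {
        at <- sample.int(nrow(segs), n_dnm, replace = TRUE, prob = len)
        pos <- floor(segs$start[at] + stats::runif(n_dnm) * len[at]) + 1
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = segs$chrom[at], pos = pos, type = "dnm", AC = 1)
      }

      ## gene conversions on segregating sites within true segments:
      ## index ranges per segment on the per-chromosome sorted panel
      conv_lo <- integer(nrow(segs)); conv_hi <- integer(nrow(segs))
      for (r in seq_len(nrow(segs))) {
        c0 <- chrom_first[ci[r]]; c1 <- chrom_last[ci[r]]
        if (c1 < c0) { conv_lo[r] <- 1L; conv_hi[r] <- 0L; next }
        sub <- pos_by_chrom[[ci[r]]]
        conv_lo[r] <- c0 + findInterval(segs$start[r] + 0.5, sub)
        conv_hi[r] <- c0 - 1L + findInterval(segs$end[r] + 0.5, sub)
      }
      w_i <- sum(mapply(range_sum, conv_lo, conv_hi))
      n_conv <- if (w_i > 0)
        stats::rpois(1, config$conversion_rate * m_i * w_i) else 0L
      if (n_conv > 0) {
        cand <- unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                              conv_lo, conv_hi, SIMPLIFY = FALSE))
        pick <- cand[sample.int(length(cand), n_conv, replace = TRUE,
                                prob = site_hetw[cand])]
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = chrom_names[site_chrom[pick]], pos = site_pos[pick],
          type = "conversion", AC = site_ac[pick])
      }

      ## boundary-contamination heterozygotes in the over-called zones
      if (config$edge_hets_per_end > 0 && config$edge_overshoot_bp > 0) {
        zl <- pmax(segs$start - ext_l, 0); zr <- pmin(segs$end + ext_r,
                                                      genome$length_bp[ci])
        zones <- rbind(
          data.frame(chrom = segs$chrom, lo = zl, hi = segs$start),
          data.frame(chrom = segs$chrom, lo = segs$end, hi = zr))
        zones <- zones[zones$hi > zones$lo, , drop = FALSE]
        if (nrow(zones)) {
          nz <- stats::rpois(nrow(zones), config$edge_hets_per_end)
          tot <- sum(nz)
          if (tot > 0) {
            at <- rep(seq_len(nrow(zones)), nz)
            pos <- floor(zones$lo[at] +
                           stats::runif(tot) * (zones$hi[at] - zones$lo[at])) + 1
            src <- take_pool(tot)
            ev[[length(ev) + 1L]] <- data.frame(
              chrom = zones$chrom[at], pos = pos, type = "edge",
              AC = site_ac[src])
          }
        }
      }
    } else {
      obs_segs[[i]] <- segs
    }
    if (length(ev)) {
      e <- do.call(rbind, ev)
      e$individual_id <- ids[i]
      events[[i]] <- e
    }
  }

  events <- if (length(ev <- events[!vapply(events, is.null, logical(1))]))
    do.call(rbind, ev) else
    data.frame(chrom = character(0), pos = numeric(0), type = character(0),
               AC = numeric(0), individual_id = character(0))
  # drop coincident double-hits at the same (individual, site)
  events <- events[!duplicated(events[, c("individual_id", "chrom", "pos")]), ,
                   drop = FALSE]
  events$MAF <- pmin(events$AC, an - events$AC) / an
  events$dropped_fn <- stats::runif(nrow(events)) <
    fn_lookup(fn_tab, events$MAF)

  ## false positives: a fraction alpha of emitted calls, planted uniformly
  ## within each individual's observed segments
  emitted_per_ind <- table(factor(events$individual_id[!events$dropped_fn],
                                  levels = ids))
  fp <- vector("list", n)
  for (i in seq_len(n)) {
    os <- obs_segs[[i]]
    if (!nrow(os)) next
    n_fp <- stats::rpois(1, config$alpha / (1 - config$alpha) *
                           emitted_per_ind[[ids[i]]])
    if (n_fp == 0) next
    olen <- os$end - os$start
    at <- sample.int(nrow(os), n_fp, replace = TRUE, prob = olen)
    fp[[i]] <- data.frame(
      chrom = os$chrom[at],
      pos = floor(os$start[at] + stats::runif(n_fp) * olen[at]) + 1,
      type = "false_positive", AC = 1, individual_id = ids[i],
      MAF = 1 / an, dropped_fn = FALSE)
  }
  fp <- fp[!vapply(fp, is.null, logical(1))]
  ledger_events <- rbind(events,
                         if (length(fp)) do.call(rbind, fp) else NULL)
  ledger_events <- ledger_events[
    !duplicated(ledger_events[, c("individual_id", "chrom", "pos")]), ,
    drop = FALSE]
  rownames(ledger_events) <- NULL

  emitted <- ledger_events[!ledger_events$dropped_fn, , drop = FALSE]
  sub <- .rand_substitution(nrow(emitted))
  calls <- het_calls(emitted$chrom, emitted$pos, sub$ref, sub$alt,
                     emitted$individual_id, AC = emitted$AC, AN = an)

  segments <- do.call(rbind, obs_segs)
  segments <- segment_set(segments$chrom, segments$start, segments$end,
                          segments$individual_id, annotation = "observed")
  true_segments <- do.call(rbind, true_segs)
  true_segments <- segment_set(true_segments$chrom, true_segments$start,
                               true_segments$end,
                               true_segments$individual_id)

  structure(list(
    calls = calls, segments = segments, true_segments = true_segments,
    sfs = sfs_summary(pmin(site_p, 1 - site_p), total_bp),
    fn_table = fn_tab, an = an, genome = genome,
    ledger = list(
      individuals = data.frame(individual_id = ids, relationship = rels,
                               meioses = meioses),
      events = ledger_events),
    config = config), class = "az_cohort")
}

#' @export
print.az_cohort <- function(x, ...) {
  cat(sprintf(
    "az_cohort: %d individuals, %d emitted calls, %d planted events\n",
    x$config$n_individuals, nrow(x$calls), nrow(x$ledger$events)))
  invisible(x)
}

#' Simulate duplicate-sample genotype replication
#'
#' For `n_pairs` duplicated samples genotyped at a panel of segregating
#' sites, draws the true genotype at each site from Hardy-Weinberg
#' proportions of its population frequency and observes it twice with
#' independent errors: a true heterozygote is called in each duplicate with
#' probability `1 - beta`, a non-heterozygote is called heterozygous with
#' probability `alpha`. Returns the per-frequency-bin replication curve that
#' [fit_error_rates()] consumes.
#'
#' @param n_pairs number of duplicate pairs.
#' @param alpha,beta planted error rates.
#' @param n_sites panel size.
#' @param an allele number used to draw the neutral site frequencies.
#' @return List with `curve` (a [replication_curve()], bins of width 0.01)
#'   and `truth = c(alpha, beta)`.
#' @examples
#' set.seed(1)
#' d <- generate_duplicates(176, alpha = 0.01, beta = 0.09)
#' fit_error_rates(d$curve)
#' @export
generate_duplicates <- function(n_pairs = 176, alpha = 0.01, beta = 0.09,
                                n_sites = 50000, an = 1000) {
  # site frequencies drawn on the 0.01 grid the replication curve is binned
  # over (neutral 1/f weights at grid resolution), so the fitted model sees
  # the same frequencies the genotypes were generated at
  grid <- seq(0.01, 0.99, by = 0.01)
  p <- sample(grid, n_sites, replace = TRUE, prob = 1 / grid)
  h <- 2 * p * (1 - p)
  n_true <- stats::rbinom(n_sites, n_pairs, h)
  a1 <- stats::rbinom(n_sites, n_true, 1 - beta)       # true hets seen in dup1
  b1 <- stats::rbinom(n_sites, n_pairs - n_true, alpha) # FP calls in dup1
  rep_a <- stats::rbinom(n_sites, a1, 1 - beta)
  rep_b <- stats::rbinom(n_sites, b1, alpha)
  fb <- factor(match(p, grid), levels = seq_along(grid))
  n1 <- tapply(a1 + b1, fb, sum, default = 0)
  nrep <- tapply(rep_a + rep_b, fb, sum, default = 0)
  list(curve = replication_curve(grid, as.numeric(n1), as.numeric(nrep)),
       truth = c(alpha = alpha, beta = beta))
}

#' Synthetic reference sequence with tunable CpG content
#'
#' First-order Markov sequence whose CpG dinucleotide frequency is enriched
#' (or depleted) by a configurable factor relative to independence, giving
#' the spectrum-normalization machinery a non-trivial composition fixture.
#'
#' @param length sequence length (>= 3).
#' @param cpg_enrichment multiplicative enrichment of G following C
#'   (1 = independent bases).
#' @param base_freq marginal base frequencies.
#' @param name sequence name.
#' @return A [Biostrings::DNAStringSet] of one sequence.
#' @export
synth_reference <- function(length, cpg_enrichment = 1,
                            base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                            name = "chrS") {
  if (length < 3) stop("'length' must be >= 3")
  base_freq <- base_freq / sum(base_freq)
  bases <- names(base_freq)
  trans <- matrix(rep(base_freq, each = 4), 4, 4,
                  dimnames = list(bases, bases))
  trans["C", "G"] <- trans["C", "G"] * cpg_enrichment
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  u <- stats::runif(length)
  out <- integer(length)
  out[1] <- findInterval(u[1], cumsum(base_freq)) + 1L
  for (i in 2:length)
    out[i] <- findInterval(u[i], cum[out[i - 1L], ]) + 1L
  seq <- Biostrings::DNAStringSet(paste(bases[out], collapse = ""))
  names(seq) <- name
  seq
}

#' Write cohort calls as a VCF
#'
#' Minimal VCF 4.2 writer for synthetic cohorts: one record per emitted
#' heterozygous call with `AC`/`AN` INFO fields and per-sample `GT` columns
#' (`0/1` for the carrier, `0/0` elsewhere).
#'
#' @param cohort an `"az_cohort"` (or a list with `calls` and `an`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_vcf <- function(cohort, path) {
  calls <- cohort$calls
  samples <- sort(unique(calls$individual_id))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=azrate-synthetic-cohort",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  o <- order(calls$chrom, calls$pos)
  calls <- calls[o, , drop = FALSE]
  gt <- matrix("0/0", nrow = nrow(calls), ncol = length(samples))
  gt[cbind(seq_len(nrow(calls)), match(calls$individual_id, samples))] <- "0/1"
  body <- paste(calls$chrom, format(calls$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", calls$ref, calls$alt, ".", "PASS",
                sprintf("AC=%d;AN=%d", as.integer(calls$AC),
                        as.integer(calls$AN)),
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
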