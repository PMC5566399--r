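#' Heterozygous call table
#'
#' Builds and validates the table of heterozygous genotype calls used for
#' mutation counting. Positions are 1-based (as in variant files); segment
#' coordinates elsewhere are 0-based half-open, and the overlap helpers
#' convert consistently. The minor allele frequency is computed as
#' `min(AC, AN - AC) / AN`.
#'
#' @param chrom,pos call coordinates (1-based position).
#' @param ref,alt single reference / alternate nucleotides.
#' @param individual_id carrier of the heterozygous genotype.
#' @param AC,AN cohort alternate allele count and total allele number.
#' @param pass optional logical dual-caller concordance flag; calls with
#'   `pass = FALSE` are dropped by [hets_in_cores()].
#' @return A data frame of class `"het_calls"` with an added `MAF` column.
#' @export
het_calls <- function(chrom, pos, ref, alt, individual_id, AC, AN,
                      pass = TRUE) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.numeric(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   individual_id = rep_len(as.character(individual_id), n),
                   AC = rep_len(as.numeric(AC), n),
                   AN = rep_len(as.numeric(AN), n),
                   pass = rep_len(pass, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    if (any(df$AC <= 0 | df$AC >= df$AN))
      stop("allele counts must satisfy 0 < AC < AN")
    if (anyDuplicated(df[, c("chrom", "pos", "individual_id")]))
      stop("duplicated (individual, site) call")
  }
  df$MAF <- pmin(df$AC, df$AN - df$AC) / df$AN
  structure(df, class = c("het_calls", "data.frame"))
}

#' Truncate autozygous segments to their cores
#'
#' Drops segments shorter than `min_len_bp` (such short segments are too
#' often identical-by-state or reflect a much older common ancestor) and
#' trims `trim_bp` from each end of the survivors, removing boundary regions
#' where segment calling over-runs and where adjacent older IBD inflates the
#' heterozygote count.
#'
#' @param segments a [segment_set()].
#' @param min_len_bp minimum parent segment length (default 10 Mb).
#' @param trim_bp trimmed from each end (default 2 Mb); must satisfy
#'   `min_len_bp > 2 * trim_bp`.
#' @return A data frame of class `"core_segments"` with columns `chrom`,
#'   `start`, `end`, `individual_id`, `parent_len_bp`.
#' @examples
#' s <- segment_set("chr1", 0, 10e6)
#' truncate_segments(s)  # one 6 Mb core
#' @export
truncate_segments <- function(segments, min_len_bp = 10e6, trim_bp = 2e6) {
  if (trim_bp < 0) stop("'trim_bp' must be >= 0")
  if (min_len_bp <= 2 * trim_bp)
    stop("'min_len_bp' must exceed twice 'trim_bp'")
  len <- segments$end - segments$start
  keep <- len >= min_len_bp
  out <- data.frame(chrom = segments$chrom[keep],
                    start = segments$start[keep] + trim_bp,
                    end = segments$end[keep] - trim_bp,
                    individual_id = segments$individual_id[keep],
                    parent_len_bp = len[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("core_segments", "data.frame"))
}

# Interval data frame (0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# Reduced callable region from optional bait and mask interval sets, or NULL.
# Seqlevel-mismatch warnings are expected (e.g. baits absent from a
# chromosome) and suppressed.
.callable_region <- function(baits = NULL, mask = NULL) {
  callable <- NULL
  for (part in list(baits, mask)) {
    if (is.null(part)) next
    gr <- GenomicRanges::reduce(.as_granges(part))
    callable <- if (is.null(callable)) gr
                else suppressWarnings(GenomicRanges::intersect(callable, gr))
  }
  callable
}

#' Evaluated genome length L
#'
#' Total number of base pairs in which heterozygotes are counted: the
#' intersection of the autozygous core segments with the exome bait regions
#' and the callability mask, summed across individuals (a genomic position
#' autozygous in k individuals contributes k bp of mutational opportunity).
#'
#' @param cores a [truncate_segments()] result (or any interval data frame
#'   with `individual_id`).
#' @param baits,mask optional interval data frames (`chrom`, `start`, `end`,
#'   0-based half-open); `NULL` means no restriction.
#' @param per_individual if TRUE, return a named vector of per-individual
#'   lengths instead of the total.
#' @return Total evaluated bp (or a named vector).
#' @examples
#' cores <- data.frame(chrom = "chr1", start = 0, end = 100,
#'                     individual_id = "a")
#' baits <- data.frame(chrom = "chr1", start = 50, end = 200)
#' mask  <- data.frame(chrom = "chr1", start = 0, end = 75)
#' compute_L(cores, baits, mask)  # 25
#' @export
compute_L <- function(cores, baits = NULL, mask = NULL,
                      per_individual = FALSE) {
  ids <- cores$individual_id
  callable <- .callable_region(baits, mask)
  if (is.null(callable)) {
    w <- cores$end - cores$start
    per <- tapply(w, ids, sum)
  } else {
    gr <- .as_granges(cores)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, callable))
    pi <- suppressWarnings(
      GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                callable[S4Vectors::subjectHits(ov)]))
    w <- GenomicRanges::width(pi)
    per <- tapply(w, ids[S4Vectors::queryHits(ov)], sum)
    missing <- setdiff(unique(ids), names(per))
    if (length(missing)) {
      z <- stats::setNames(rep(0, length(missing)), missing)
      per <- c(per, z)
    }
  }
  per <- stats::setNames(as.numeric(per), names(per))
  if (per_individual) per else sum(per)
}

#' Restrict calls to each carrier's core segments
#'
#' Keeps heterozygous calls whose position falls inside one of the carrying
#' individual's own core segments (and, optionally, inside the callable
#' region). Calls flagged `pass = FALSE` are dropped first.
#'
#' @param calls a [het_calls()] table.
#' @param cores a [truncate_segments()] result.
#' @param baits,mask optional interval data frames restricting callability.
#' @return The filtered `het_calls` subset.
#' @export
hets_in_cores <- function(calls, cores, baits = NULL, mask = NULL) {
  if (!nrow(calls)) return(calls)
  if (!is.null(calls$pass)) calls <- calls[calls$pass, , drop = FALSE]
  if (!nrow(calls) || !nrow(cores)) return(calls[integer(0), , drop = FALSE])
  gr_calls <- GenomicRanges::GRanges(calls$chrom,
                                     IRanges::IRanges(calls$pos, calls$pos))
  gr_cores <- .as_granges(cores)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_calls, gr_cores))
  same <- calls$individual_id[S4Vectors::queryHits(ov)] ==
    cores$individual_id[S4Vectors::subjectHits(ov)]
  keep <- unique(S4Vectors::queryHits(ov)[same])
  out <- calls[keep, , drop = FALSE]
  callable <- .callable_region(baits, mask)
  if (!is.null(callable) && nrow(out)) {
    gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
    out <- out[suppressWarnings(IRanges::overlapsAny(gr, callable)), ,
               drop = FALSE]
  }
  out
}

#' Count qualifying heterozygotes N
#'
#' @param calls a [het_calls()] table.
#' @param cores a [truncate_segments()] result.
#' @param maf_max count calls with `MAF <= maf_max` (ignored when
#'   `singleton_only = TRUE`).
#' @param singleton_only count only cohort singletons (`AC == 1`).
#' @return Integer count.
#' @export
count_hets <- function(calls, cores, maf_max = NULL, singleton_only = FALSE) {
  x <- hets_in_cores(calls, cores)
  if (singleton_only) return(sum(x$AC == 1))
  if (is.null(maf_max)) return(nrow(x))
  sum(x$MAF <= maf_max)
}

#' Singleton mutation-rate estimate
#'
#' Point estimate of the per-bp per-generation mutation rate from the count
#' of singleton heterozygotes inside autozygous cores,
#' `N0`, the evaluated length `L` and the mean separating meioses `M`.
#' Two error-correction conventions are provided:
#'
#' * `mode = "standard"`: `mu = N0 (1 - alpha) / ((1 - beta) L M)` —
#'   false positives removed from the count, then inflated for the
#'   false-negative rate (the statistically conventional correction).
#' * `mode = "paper"`: `mu = N0 (1 - alpha) (1 - beta) / (L M)` — the
#'   multiplicative form that reproduces the printed worked example
#'   1.51e-8 from `N0 = 1152`, `L = 9.46e9`, `M = 6.63`, `alpha = 0.01`,
#'   `beta = 0.17`.
#'
#' @param N0 singleton heterozygote count.
#' @param L evaluated length in bp.
#' @param M mean number of separating meioses.
#' @param alpha,beta false-positive and false-negative rates.
#' @param mode `"standard"` (default) or `"paper"`.
#' @return Mutation rate per bp per generation.
#' @examples
#' estimate_rate_singleton(1152, 9.46e9, 6.63, 0.01, 0.17, "paper")
#' @export
estimate_rate_singleton <- function(N0, L, M, alpha = 0, beta = 0,
                                    mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  if (L <= 0 || M <= 0) stop("L and M must be positive")
  if (mode == "standard") N0 * (1 - alpha) / ((1 - beta) * L * M)
  else N0 * (1 - alpha) * (1 - beta) / (L * M)
}

#' Trio-based rate check
#'
#' The per-bp per-generation mutation rate implied by a count of validated de
#' novo mutations in parent-offspring trios: each trio offspring contributes
#' two haploid genomes of callable opportunity for one generation, so
#' `mu = n / (2 * n_trios * callable_bp)`, with Poisson standard deviation
#' `sqrt(n)` on the count.
#'
#' @param n_dnm validated de novo mutation count in the callable region.
#' @param n_trios number of trios.
#' @param callable_bp callable length per haploid genome (bp).
#' @return List with `mu` and `sd`.
#' @examples
#' trio_rate(17, 15, 45e6)  # ~1.3e-8 +- 0.3e-8
#' @export
trio_rate <- function(n_dnm, n_trios, callable_bp) {
  denom <- 2 * n_trios * callable_bp
  list(mu = n_dnm / denom, sd = sqrt(n_dnm) / denom)
}

#' Cumulative heterozygosity summary of the site frequency spectrum
#'
#' `Pi(f)` is the expected per-bp heterozygosity contributed by segregating
#' sites of minor allele frequency at most `f`:
#' `Pi(f) = sum_{sites: MAF <= f} 2 p (1 - p) / callable_bp`. It calibrates
#' the conversion-rate estimator: the per-bp probability that a non-crossover
#' gene-conversion event creates a heterozygote at a site of MAF at most `f`
#' is proportional to `Pi(f)`.
#'
#' @param maf minor allele frequencies of all segregating sites.
#' @param callable_bp the callable length the sites were ascertained in.
#' @return An object of class `"sfs_summary"`; use [pi_f()] to evaluate.
#' @export
sfs_summary <- function(maf, callable_bp) {
  if (any(maf < 0 | maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  o <- order(maf)
  maf <- maf[o]
  cum <- cumsum(2 * maf * (1 - maf)) / callable_bp
  structure(list(maf = maf, cum_het = cum, callable_bp = callable_bp,
                 total = if (length(cum)) cum[length(cum)] else 0),
            class = "sfs_summary")
}

#' @export
print.sfs_summary <- function(x, ...) {
  cat(sprintf("sfs_summary: %d sites, heterozygosity %.3g per bp\n",
              length(x$maf), x$total))
  invisible(x)
}

#' @rdname sfs_summary
#' @param sfs an `"sfs_summary"` object.
#' @param f frequency threshold(s).
#' @return `pi_f()` returns `Pi(f)` (vectorized).
#' @export
pi_f <- function(sfs, f) {
  idx <- findInterval(f, sfs$maf)
  ifelse(idx == 0, 0, sfs$cum_het[pmax(idx, 1)])
}

#' MAF-threshold regression
#'
#' For a grid of minor-allele-frequency thresholds `f`, computes the apparent
#' mutation rate from the heterozygotes with `MAF <= f` inside the autozygous
#' cores and regresses it on `f`. Heterozygotes introduced by gene conversion
#' accumulate in proportion to the available segregating variation below the
#' threshold, so the regression separates mutation — the intercept at
#' `f = 0` — from gene conversion — the slope. Each counted call is
#' individually corrected for the frequency-resolved false-negative rate
#' (weight `1 / (1 - beta(MAF))`), and the false-positive correction
#' `(1 - alpha)` is applied uniformly:
#' `rate(f) = (1 - alpha) / (L M) * sum_{MAF <= f} 1 / (1 - beta_i)`.
#'
#' @param calls in-core heterozygous calls (see [hets_in_cores()]).
#' @param L evaluated length in bp (see [compute_L()]).
#' @param M mean separating meioses (see [weighted_mean_meioses()]).
#' @param fn_table an [fn_table()] covering the MAF range of the calls.
#' @param alpha false-positive rate.
#' @param f_grid thresholds; default 0.10 to 0.50 in steps of 0.01.
#' @return List of class `"maf_regression"`: `intercept` (the
#'   conversion-corrected mutation rate), `slope` (per unit allele
#'   frequency), and `grid` (data frame `f`, `n_f`, `rate`).
#' @export
maf_threshold_regression <- function(calls, L, M, fn_table, alpha = 0.01,
                                     f_grid = seq(0.10, 0.50, by = 0.01)) {
  if (any(f_grid <= 0 | f_grid > 0.5)) stop("'f_grid' must lie in (0, 0.5]")
  w <- 1 / (1 - fn_lookup(fn_table, calls$MAF))
  cnt <- vapply(f_grid, function(f) sum(calls$MAF <= f), numeric(1))
  wsum <- vapply(f_grid, function(f) sum(w[calls$MAF <= f]), numeric(1))
  if (sum(cnt > 0) < 3)
    stop("fewer than 3 grid points with nonzero counts")
  rate <- wsum * (1 - alpha) / (L * M)
  fit <- stats::lm(rate ~ f_grid)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 grid = data.frame(f = f_grid, n_f = cnt, rate = rate)),
            class = "maf_regression")
}

#' Gene-conversion rate from the regression slope
#'
#' Linearized calibration of the MAF-threshold regression slope: over the
#' regression window the per-bp per-meiosis probability that a conversion
#' event produces a heterozygote at MAF at most `f` is `c * Pi(f)`, so the
#' fitted slope in rate-per-unit-frequency converts to a per-bp
#' per-generation conversion rate as
#' `c = slope * (f_hi - f_lo) / (Pi(f_hi) - Pi(f_lo))`.
#'
#' @param slope slope from [maf_threshold_regression()].
#' @param sfs an [sfs_summary()] of the cohort's segregating sites.
#' @param f_lo,f_hi the regression window (defaults 0.10 and 0.50).
#' @return Conversion rate `c` per bp per generation.
#' @export
conversion_rate_from_slope <- function(slope, sfs, f_lo = 0.10, f_hi = 0.50) {
  dpi <- pi_f(sfs, f_hi) - pi_f(sfs, f_lo)
  if (dpi <= 0)
    stop("flat cumulative heterozygosity over the regression window")
  slope * (f_hi - f_lo) / dpi
}

#' Bootstrap standard error over resampled units
#'
#' Resamples the supplied units (typically individual ids — individuals are
#' the independent sampling units; their segments and calls travel with
#' them) with replacement, recomputes the statistic and returns the standard
#' deviation across replicates.
#'
#' @param units vector of exchangeable units.
#' @param statistic function of a resampled unit vector returning a scalar.
#' @param B number of bootstrap replicates (>= 100).
#' @return The bootstrap standard error (scalar). Fails with diagnostics if
#'   more than 10 percent of replicates error.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' bootstrap_se(x, mean, B = 200)  # ~ 1/sqrt(100)
#' @export
bootstrap_se <- function(units, statistic, B = 1000) {
  if (B < 100) stop("B must be >= 100")
  n <- length(units)
  vals <- rep(NA_real_, B)
  errs <- character(0)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(statistic(units[idx]),
                  error = function(e) { errs <<- c(errs, conditionMessage(e))
                                        NA_real_ })
    vals[b] <- v
  }
  nf <- sum(is.na(vals))
  if (nf > 0.1 * B)
    stop(sprintf("statistic failed on %d/%d bootstrap replicates; first: %s",
                 nf, B, if (length(errs)) errs[1] else "NA produced"))
  stats::sd(vals[!is.na(vals)])
}

#' Full rate-estimation pipeline with bootstrap uncertainty
#'
#' Runs segment truncation, evaluated-length computation, heterozygote
#' counting, the singleton estimator, the MAF-threshold regression and the
#' conversion-rate calibration, with individual-level bootstrap standard
#' errors for all headline quantities.
#'
#' @param calls a [het_calls()] table (cohort-wide).
#' @param segments a [segment_set()] (all individuals).
#' @param fn_table an [fn_table()] covering all call frequencies.
#' @param alpha false-positive rate.
#' @param sfs an [sfs_summary()] of the cohort's segregating sites; required
#'   for the conversion rate.
#' @param assignments optional [classify_cohort()] result supplying
#'   per-individual posterior-mean meioses; alternatively give a fixed `M`.
#' @param M fixed mean separating meioses (used when `assignments` is NULL).
#' @param baits,mask optional callability restrictions (see [compute_L()]).
#' @param min_len_bp,trim_bp segment filters (see [truncate_segments()]).
#' @param f_grid,f_lo,f_hi regression window.
#' @param mode singleton correction mode (see [estimate_rate_singleton()]).
#' @param B bootstrap replicates (0 skips the bootstrap).
#' @return An object of class `"rate_estimate"`: list with `mu_singleton`,
#'   `mu_intercept`, `slope`, `conversion_rate`, their `se_*` companions,
#'   `N0`, `L`, `M`, `mode`, and the regression `grid`.
#' @export
estimate_rates <- function(calls, segments, fn_table, alpha = 0.01,
                           sfs = NULL, assignments = NULL, M = NULL,
                           baits = NULL, mask = NULL,
                           min_len_bp = 10e6, trim_bp = 2e6,
                           f_grid = seq(0.10, 0.50, by = 0.01),
                           f_lo = 0.10, f_hi = 0.50,
                           mode = c("standard", "paper"), B = 1000) {
  mode <- match.arg(mode)
  if (is.null(assignments) && is.null(M))
    stop("supply either 'assignments' or a fixed 'M'")
  cores <- truncate_segments(segments, min_len_bp, trim_bp)
  L_ind <- compute_L(cores, baits, mask, per_individual = TRUE)
  ids <- names(L_ind)[L_ind > 0]
  L_ind <- L_ind[ids]
  if (!length(ids)) stop("no individual contributes evaluated length")
  M_ind <- if (!is.null(assignments)) {
    mm <- stats::setNames(assignments$M_post, assignments$individual_id)
    if (any(!ids %in% names(mm)))
      stop("assignments missing for some individuals with core segments")
    mm[ids]
  } else stats::setNames(rep(M, length(ids)), ids)

  incore <- hets_in_cores(calls, cores, baits, mask)
  incore <- incore[incore$individual_id %in% ids, , drop = FALSE]
  an <- if (nrow(calls)) max(calls$AN) else 2
  maf_singleton <- 1 / an
  beta0 <- fn_lookup(fn_table, maf_singleton)
  w <- 1 / (1 - fn_lookup(fn_table, incore$MAF))

  # per-individual pieces so the bootstrap is a cheap re-aggregation
  n0_ind <- stats::setNames(numeric(length(ids)), ids)
  t0 <- tapply(incore$AC == 1, incore$individual_id, sum)
  n0_ind[names(t0)] <- t0
  wmat <- matrix(0, nrow = length(ids), ncol = length(f_grid),
                 dimnames = list(ids, NULL))
  for (j in seq_along(f_grid)) {
    sel <- incore$MAF <= f_grid[j]
    tj <- tapply(w[sel], incore$individual_id[sel], sum)
    wmat[names(tj), j] <- tj
  }

  dpi <- if (!is.null(sfs)) pi_f(sfs, f_hi) - pi_f(sfs, f_lo) else NA_real_
  fbar <- mean(f_grid); fvar <- sum((f_grid - fbar)^2)

  agg <- function(idx) {
    L <- sum(L_ind[idx])
    Mbar <- sum(L_ind[idx] * M_ind[idx]) / L
    N0 <- sum(n0_ind[idx])
    rates <- colSums(wmat[idx, , drop = FALSE]) * (1 - alpha) / (L * Mbar)
    slope <- sum((f_grid - fbar) * (rates - mean(rates))) / fvar
    intercept <- mean(rates) - slope * fbar
    mu0 <- if (mode == "standard") N0 * (1 - alpha) / ((1 - beta0) * L * Mbar)
           else N0 * (1 - alpha) * (1 - beta0) / (L * Mbar)
    conv <- if (!is.na(dpi) && dpi > 0) slope * (f_hi - f_lo) / dpi
            else NA_real_
    c(mu_singleton = mu0, mu_intercept = intercept, slope = slope,
      conversion_rate = conv, N0 = N0, L = L, M = Mbar)
  }
  est <- agg(ids)
  se <- rep(NA_real_, 4)
  names(se) <- c("mu_singleton", "mu_intercept", "slope", "conversion_rate")
  if (B >= 100) {
    reps <- matrix(NA_real_, nrow = B, ncol = 4)
    for (b in seq_len(B)) {
      idx <- sample(ids, length(ids), replace = TRUE)
      reps[b, ] <- agg(idx)[1:4]
    }
    se <- apply(reps, 2, stats::sd)
    names(se) <- c("mu_singleton", "mu_intercept", "slope", "conversion_rate")
  }
  structure(list(mu_singleton = unname(est["mu_singleton"]),
                 mu_intercept = unname(est["mu_intercept"]),
                 slope = unname(est["slope"]),
                 conversion_rate = unname(est["conversion_rate"]),
                 se_mu_singleton = unname(se["mu_singleton"]),
                 se_mu_intercept = unname(se["mu_intercept"]),
                 se_slope = unname(se["slope"]),
                 se_conversion_rate = unname(se["conversion_rate"]),
                 N0 = unname(est["N0"]), L = unname(est["L"]),
                 M = unname(est["M"]), mode = mode, alpha = alpha,
                 grid = data.frame(f = f_grid)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("rate_estimate\n")
  cat(sprintf("  singleton mu : %.3g +- %.2g (N0 = %d, mode %s)\n",
              x$mu_singleton, x$se_mu_singleton, round(x$N0), x$mode))
  cat(sprintf("  intercept mu : %.3g +- %.2g\n",
              x$mu_intercept, x$se_mu_intercept))
  cat(sprintf("  slope        : %.3g +- %.2g per unit MAF\n",
              x$slope, x$se_slope))
  cat(sprintf("  conversion c : %.3g +- %.2g\n",
              x$conversion_rate, x$se_conversion_rate))
  cat(sprintf("  L = %.4g bp, M = %.3f\n", x$L, x$M))
  invisible(x)
}

#' Read heterozygous calls from a VCF
#'
#' Extracts, for every sample, the sites genotyped heterozygous (GT `0/1` or
#' `1/0`), together with the cohort `AC`/`AN` INFO fields, into a
#' [het_calls()] table. Multi-allelic records are skipped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A [het_calls()] table.
#' @export
read_calls_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "cohort")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- rep(NA_character_, length(rr))
  one_alt <- lengths(rr$ALT) == 1
  alt[one_alt] <- as.character(unlist(rr$ALT[one_alt]))
  biallelic <- one_alt & !is.na(alt) &
    nchar(as.character(rr$REF)) == 1 & nchar(alt) == 1
  gt <- VariantAnnotation::geno(vcf)$GT
  info <- VariantAnnotation::info(vcf)
  ac <- vapply(info$AC, function(x) as.numeric(x[1]), numeric(1))
  an <- as.numeric(info$AN)
  rows <- list()
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  dim(het) <- dim(gt)
  idx <- which(het & biallelic, arr.ind = TRUE)
  if (nrow(idx)) {
    rows <- het_calls(
      chrom = as.character(GenomicRanges::seqnames(rr))[idx[, 1]],
      pos = GenomicRanges::start(rr)[idx[, 1]],
      ref = as.character(rr$REF)[idx[, 1]],
      alt = as.character(alt)[idx[, 1]],
      individual_id = colnames(gt)[idx[, 2]],
      AC = ac[idx[, 1]], AN = an[idx[, 1]])
    rows
  } else {
    het_calls(character(0), numeric(0), character(0), character(0),
              character(0), numeric(0), numeric(0))
  }
}
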