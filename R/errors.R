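#' Expected replication rate of a heterozygous call between duplicates
#'
#' Probability that a site called heterozygous in one duplicate sample is
#' called heterozygous again in the second, under a model with false-positive
#' rate `alpha` (a non-heterozygous site is called het), false-negative rate
#' `beta` (a true heterozygote is missed), errors independent between
#' duplicates, and a Hardy-Weinberg prior `h = 2 f (1 - f)` that the
#' individual is truly heterozygous at a site of population allele frequency
#' `f`:
#'
#' \deqn{R(f) = \frac{h (1-\beta)^2 + (1-h)\alpha^2}
#'                   {h (1-\beta) + (1-h)\alpha}}
#'
#' `R(f)` tends to `alpha` as `f` tends to 0 and is close to `1 - beta` for
#' common variants when `alpha` is small.
#'
#' @param alpha false-positive rate, in (0, 1).
#' @param beta false-negative rate, in (0, 1).
#' @param f population allele frequency (vectorized), in `[0, 1]`.
#' @return Vector of replication probabilities.
#' @examples
#' predict_replication(0.01, 0.17, 0.2)  # ~0.81
#' @export
predict_replication <- function(alpha, beta, f) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("'alpha' and 'beta' must lie in [0, 1]")
  if (any(f < 0 | f > 1)) stop("'f' must lie in [0, 1]")
  h <- 2 * f * (1 - f)
  num <- h * (1 - beta)^2 + (1 - h) * alpha^2
  den <- h * (1 - beta) + (1 - h) * alpha
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning("zero denominator (f = 0 with alpha = 0): replication set to 0")
  out
}

#' Construct a replication curve
#'
#' @param f allele-frequency bin centres, strictly increasing in (0, 1).
#' @param n_het_dup1 heterozygous calls observed in duplicate 1 per bin.
#' @param n_replicated how many of those replicated in duplicate 2.
#' @return A data frame of class `"replication_curve"`.
#' @export
replication_curve <- function(f, n_het_dup1, n_replicated) {
  if (is.unsorted(f, strictly = TRUE)) stop("'f' must be strictly increasing")
  if (any(n_replicated > n_het_dup1))
    stop("replicated counts cannot exceed observed counts")
  structure(data.frame(f = f, n_het_dup1 = n_het_dup1,
                       n_replicated = n_replicated),
            class = c("replication_curve", "data.frame"))
}

#' Jointly fit the false-positive and false-negative rate
#'
#' Fits `(alpha, beta)` to an observed duplicate-sample replication curve by
#' minimizing the count-weighted squared deviation between the empirical
#' per-bin replication fraction and [predict_replication()], subject to the
#' box constraint `(0, 1)^2`. The observed curve over ~100 allele-frequency
#' bins is an overconstrained system in the two unknowns; a deterministic
#' 5 x 5 multi-start grid over `(0.005, 0.3)^2` followed by bounded local
#' refinement makes the solution reproducible and robust.
#'
#' @param curve a [replication_curve()] (columns `f`, `n_het_dup1`,
#'   `n_replicated`). Bins with zero observed calls are dropped.
#' @param weights `"count"` (default) weights each bin by `n_het_dup1`;
#'   `"equal"` weights all non-empty bins equally.
#' @return An object of class `"error_rates"`: list with `alpha`, `beta`,
#'   `residual_norm` (weighted RSS at the optimum), `n_bins`, `boundary`
#'   (TRUE if the fit ran into the box constraint, e.g. for a degenerate
#'   perfectly-replicating curve) and `weights`.
#' @examples
#' f <- seq(0.01, 0.99, 0.01)
#' curve <- replication_curve(f, rep(1000, 99),
#'                            round(1000 * predict_replication(0.01, 0.09, f)))
#' fit_error_rates(curve)
#' @export
fit_error_rates <- function(curve, weights = c("count", "equal")) {
  weights <- match.arg(weights)
  keep <- curve$n_het_dup1 > 0
  curve <- curve[keep, , drop = FALSE]
  if (nrow(curve) < 2 || length(unique(curve$f)) < 2)
    stop("non-identifiable replication curve: need >= 2 non-empty bins")
  f <- curve$f
  obs <- curve$n_replicated / curve$n_het_dup1
  w <- if (weights == "count") curve$n_het_dup1 else rep(1, nrow(curve))
  obj <- function(p) {
    r <- predict_replication(p[1], p[2], f)
    sum(w * (obs - r)^2)
  }
  starts <- as.matrix(expand.grid(alpha = seq(0.005, 0.3, length.out = 5),
                                  beta = seq(0.005, 0.3, length.out = 5)))
  eps <- 1e-9
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::nlminb(starts[s, ], obj, lower = c(eps, eps),
                         upper = c(1 - eps, 1 - eps),
                         control = list(abs.tol = 1e-18, rel.tol = 1e-14,
                                        x.tol = 1e-14, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  boundary <- any(best$par <= 2 * eps) || any(best$par >= 1 - 2 * eps)
  structure(list(alpha = unname(best$par[1]), beta = unname(best$par[2]),
                 residual_norm = best$objective, n_bins = nrow(curve),
                 boundary = boundary, weights = weights),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("error_rates: alpha = %.4g, beta = %.4g (%d bins, wRSS %.3g%s)\n",
              x$alpha, x$beta, x$n_bins, x$residual_norm,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' A binomial genotype-caller abstraction
#'
#' Calls a site heterozygous when at least `min_alt` reads carry the
#' alternate base and the alternate read fraction is at least `min_frac`.
#' Used by [spike_in_recall()]; any function mapping
#' `(alt_reads, depth) -> logical` can be substituted.
#'
#' @param min_alt minimum alternate read count.
#' @param min_frac minimum alternate read fraction.
#' @return A vectorized function `(alt, depth) -> logical`.
#' @export
binomial_caller <- function(min_alt = 2, min_frac = 0.2) {
  force(min_alt); force(min_frac)
  function(alt, depth) alt >= min_alt & alt >= min_frac * depth
}

#' Spike-in estimate of the false-negative rate
#'
#' Emulates the read-level spike-in experiment: at each selected site an
#' alternate base is chosen (transition with probability 2/3, transversion
#' 1/3) and every read covering the site is switched to that base
#' independently with probability `p_alt = 0.5`, mimicking a true
#' heterozygote. A genotype caller is applied to the resulting alternate
#' read counts and the false-negative rate is the fraction of sites not
#' recalled as heterozygous.
#'
#' @param depth integer vector of per-site read depths (one site each).
#' @param ref optional vector of reference bases (A/C/G/T) used to draw the
#'   alternate base; defaults to random bases.
#' @param p_alt per-read probability of carrying the alternate base.
#' @param caller a function `(alt, depth) -> logical`, see
#'   [binomial_caller()].
#' @return List with `fn_rate`, and a data frame `sites`
#'   (`depth`, `ref`, `alt`, `alt_reads`, `called_het`).
#' @examples
#' set.seed(1)
#' spike_in_recall(rpois(1000, 27) + 1)$fn_rate
#' @export
spike_in_recall <- function(depth, ref = NULL, p_alt = 0.5,
                            caller = binomial_caller()) {
  n <- length(depth)
  if (n < 1) stop("need at least one site")
  if (any(depth < 1)) stop("all sites must have depth >= 1")
  bases <- c("A", "C", "G", "T")
  if (is.null(ref)) ref <- sample(bases, n, replace = TRUE)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  is_ts <- stats::runif(n) < 2 / 3
  alt <- character(n)
  alt[is_ts] <- transition[ref[is_ts]]
  if (any(!is_ts)) {
    tv <- ref[!is_ts]
    pick <- ifelse(stats::runif(length(tv)) < 0.5, 1L, 2L)
    alt[!is_ts] <- mapply(function(b, p) transversions[[b]][p], tv, pick)
  }
  alt_reads <- stats::rbinom(n, size = depth, prob = p_alt)
  called <- caller(alt_reads, depth)
  list(fn_rate = mean(!called),
       sites = data.frame(depth = depth, ref = ref, alt = alt,
                          alt_reads = alt_reads, called_het = called))
}

#' Frequency-resolved false-negative table
#'
#' Joint variant calling recalls rare variants less reliably than common
#' ones, so the false-negative rate is carried as a table of
#' allele-frequency bands. Bands are half-open `[lo, hi)` on the minor
#' allele frequency scale, except that the last band includes its upper
#' boundary.
#'
#' @param lo,hi band boundaries (MAF), non-overlapping and ordered.
#' @param beta false-negative rate per band, each in (0, 1).
#' @return A data frame of class `"fn_table"`.
#' @examples
#' fn_table(c(0, 0.002, 0.10), c(0.002, 0.10, 0.50), c(0.17, 0.12, 0.079))
#' @export
fn_table <- function(lo, hi, beta) {
  stopifnot(length(lo) == length(hi), length(lo) == length(beta))
  if (any(beta <= 0 | beta >= 1)) stop("each beta must lie in (0, 1)")
  if (any(hi <= lo)) stop("bands must satisfy lo < hi")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; beta <- beta[o]
  if (any(lo[-1] < hi[-length(hi)])) stop("bands must not overlap")
  structure(data.frame(lo = lo, hi = hi, beta = beta),
            class = c("fn_table", "data.frame"))
}

#' Look up the false-negative rate for given allele frequencies
#'
#' @param table an [fn_table()].
#' @param maf minor allele frequencies (vectorized).
#' @return Vector of `beta` values; an error if a frequency is not covered.
#' @export
fn_lookup <- function(table, maf) {
  idx <- findInterval(maf, table$lo)
  bad <- idx == 0 | maf > table$hi[pmax(idx, 1)]
  if (any(bad))
    stop("allele frequency not covered by the FN table: ",
         paste(utils::head(signif(maf[bad], 3), 5), collapse = ", "))
  table$beta[idx]
}
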