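const_fn <- function(beta) fn_table(0, 0.5, beta)

test_that("segment truncation drops short segments and trims survivors", {
  s <- segment_set("chr1", c(0, 20e6, 50e6), c(10e6, 29.99e6, 65e6),
                   c("a", "a", "b"))
  cores <- truncate_segments(s)
  expect_equal(nrow(cores), 2)  # the 9.99 Mb segment is dropped
  expect_equal(cores$end - cores$start, c(6e6, 11e6))
  expect_equal(cores$start, c(2e6, 52e6))
  # identity when both thresholds are zero
  id <- truncate_segments(s, min_len_bp = 1, trim_bp = 0)
  expect_equal(id$start, s$start)
  expect_equal(id$end, s$end)
  expect_error(truncate_segments(s, min_len_bp = 4e6, trim_bp = 2e6),
               "exceed")
})

test_that("compute_L intersects cores, baits and mask", {
  cores <- data.frame(chrom = "chr1", start = 0, end = 100,
                      individual_id = "a")
  baits <- data.frame(chrom = "chr1", start = 50, end = 200)
  mask <- data.frame(chrom = "chr1", start = 0, end = 75)
  expect_equal(compute_L(cores, baits, mask), 25)
  expect_equal(compute_L(cores, data.frame(chrom = "chr2", start = 0,
                                           end = 1e6), NULL), 0)
  expect_equal(compute_L(cores), 100)
  # one bp autozygous in two individuals counts twice
  two <- rbind(cores, transform(cores, individual_id = "b"))
  expect_equal(compute_L(two, baits, mask), 50)
  expect_equal(compute_L(two, baits, mask, per_individual = TRUE),
               c(a = 25, b = 25))
})

test_that("compute_L equals a per-bp bitmap oracle on random fixtures", {
  set.seed(30)
  universe <- 5000
  rand_iv <- function(n) {  # possibly overlapping intervals
    start <- sort(sample.int(universe - 10, n))
    data.frame(chrom = "c1", start = start,
               end = pmin(start + sample.int(400, n, replace = TRUE),
                          universe))
  }
  disjoint_iv <- function(n) {  # cores must not overlap within an individual
    b <- sort(sample.int(universe, 2 * n))
    data.frame(chrom = "c1", start = b[seq(1, 2 * n, 2)],
               end = b[seq(2, 2 * n, 2)])
  }
  bitmap <- function(iv) {
    v <- logical(universe)
    for (r in seq_len(nrow(iv))) if (iv$end[r] > iv$start[r])
      v[(iv$start[r] + 1):iv$end[r]] <- TRUE
    v
  }
  for (rep in 1:5) {
    cores_a <- disjoint_iv(6); cores_a$individual_id <- "a"
    cores_b <- disjoint_iv(4); cores_b$individual_id <- "b"
    baits <- rand_iv(5); mask <- rand_iv(7)
    expected <- sum(bitmap(cores_a) & bitmap(baits) & bitmap(mask)) +
      sum(bitmap(cores_b) & bitmap(baits) & bitmap(mask))
    cores <- rbind(cores_a, cores_b)
    expect_equal(compute_L(cores, baits, mask), expected)
  }
})

test_that("het calls validate and carry MAF", {
  expect_error(het_calls("c1", 5, "A", "A", "x", 1, 10), "differ")
  expect_error(het_calls("c1", 5, "A", "G", "x", 0, 10), "0 < AC < AN")
  expect_error(het_calls("c1", c(5, 5), "A", "G", "x", 1, 10), "duplicated")
  calls <- het_calls("c1", c(5, 9), "A", "G", c("x", "y"), c(1, 9), 10)
  expect_equal(calls$MAF, c(0.1, 0.1))
})

test_that("in-core filtering respects individual identity and pass flags", {
  cores <- truncate_segments(segment_set("c1", c(0, 0), c(10e6, 10e6),
                                         c("a", "b")),
                             min_len_bp = 10e6, trim_bp = 2e6)
  calls <- het_calls(rep("c1", 4), c(5e6, 5e6, 1e6, 5.1e6),
                     "A", "G", c("a", "b", "a", "c"), 1, 1000)
  kept <- hets_in_cores(calls, cores)
  # the two mid-core calls stay, the edge call and foreign individual drop
  expect_equal(sort(kept$individual_id), c("a", "b"))
  calls$pass <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(hets_in_cores(calls, cores)$individual_id, "a")
})

test_that("count_hets equals a brute-force nested scan on random cohorts", {
  set.seed(31)
  for (rep in 1:4) {
    n_ind <- 5
    cores <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
      start <- sort(sample.int(8000, 3)) * 10
      data.frame(chrom = sample(c("c1", "c2"), 3, replace = TRUE),
                 start = start, end = start + sample(200:900, 3),
                 individual_id = paste0("i", i))
    }))
    an <- 100
    calls <- het_calls(sample(c("c1", "c2"), 400, replace = TRUE),
                       sample.int(90000, 400), "A", "G",
                       sample(paste0("i", 1:n_ind), 400, replace = TRUE),
                       sample.int(an - 1, 400, replace = TRUE), an)
    brute <- function(maf_max = NULL, singleton = FALSE) {
      cnt <- 0
      for (r in seq_len(nrow(calls))) {
        inside <- FALSE
        for (q in seq_len(nrow(cores))) {
          if (calls$individual_id[r] == cores$individual_id[q] &&
              calls$chrom[r] == cores$chrom[q] &&
              calls$pos[r] > cores$start[q] && calls$pos[r] <= cores$end[q])
            inside <- TRUE
        }
        if (!inside) next
        if (singleton) { if (calls$AC[r] == 1) cnt <- cnt + 1 }
        else if (is.null(maf_max) || calls$MAF[r] <= maf_max) cnt <- cnt + 1
      }
      cnt
    }
    expect_equal(count_hets(calls, cores), brute())
    expect_equal(count_hets(calls, cores, maf_max = 0.2), brute(0.2))
    expect_equal(count_hets(calls, cores, singleton_only = TRUE),
                 brute(singleton = TRUE))
  }
})

test_that("singleton estimator reproduces both correction conventions", {
  # printed worked example, multiplicative convention
  mu_paper <- estimate_rate_singleton(1152, 9.46e9, 6.63, 0.01, 0.17, "paper")
  expect_equal(signif(mu_paper, 3), 1.51e-8)
  # conventional correction on the same inputs
  mu_std <- estimate_rate_singleton(1152, 9.46e9, 6.63, 0.01, 0.17)
  expect_equal(mu_std, 1152 * 0.99 / (0.83 * 9.46e9 * 6.63))
  expect_equal(signif(mu_std, 3), 2.19e-8)
  expect_equal(estimate_rate_singleton(0, 1e9, 6, 0.01, 0.17), 0)
  expect_error(estimate_rate_singleton(10, 0, 6), "positive")
})

test_that("trio worked examples give ~1.3e-8 with Poisson uncertainty", {
  r1 <- trio_rate(17, 15, 45e6)
  expect_equal(round(r1$mu * 1e8, 1), 1.3)
  expect_equal(round(r1$sd * 1e8, 1), 0.3)
  r2 <- trio_rate(32, 15, 82e6)
  expect_equal(round(r2$mu * 1e8, 1), 1.3)
  expect_equal(round(r2$sd * 1e8, 2), 0.23)
})

test_that("sfs summary accumulates heterozygosity monotonically", {
  sfs <- sfs_summary(c(0.1, 0.3, 0.2, 0.5), callable_bp = 100)
  expect_equal(pi_f(sfs, 0.05), 0)
  expect_equal(pi_f(sfs, 0.1), 2 * 0.1 * 0.9 / 100)
  expect_equal(pi_f(sfs, 0.5), sfs$total)
  expect_equal(sfs$total,
               sum(2 * c(0.1, 0.2, 0.3, 0.5) *
                     (1 - c(0.1, 0.2, 0.3, 0.5))) / 100)
  f <- seq(0, 0.5, 0.01)
  expect_true(all(diff(pi_f(sfs, f)) >= 0))
  expect_error(sfs_summary(0.7, 10), "MAF")
})

test_that("regression is exact on a linear fixture", {
  # counts rise by exactly 2 per 0.01 of threshold: N(f) = 80 + 200 f
  an <- 10000
  # 98 calls below the window, then 2 at each grid point:
  # N(f) = 98 + 2 (1 + 100 (f - 0.10)) = 80 + 200 f on the grid
  maf <- c(rep(0.05, 98), rep(seq(0.10, 0.50, 0.01), each = 2))
  calls <- het_calls("c1", seq_along(maf), "A", "G",
                     paste0("x", seq_along(maf)),
                     AC = round(maf * an), AN = an)
  calls$MAF <- maf  # exact grid values
  L <- 1e9; M <- 6
  beta <- 0.2; alpha <- 0.01
  reg <- maf_threshold_regression(calls, L, M, const_fn(beta), alpha = alpha)
  scale <- (1 - alpha) / ((1 - beta) * L * M)
  expect_equal(reg$intercept, 80 * scale, tolerance = 1e-12)
  expect_equal(reg$slope, 200 * scale, tolerance = 1e-12)
  # only two grid points (0.49, 0.50) see a nonzero count
  high <- calls[1:2, ]; high$MAF <- c(0.49, 0.49)
  expect_error(maf_threshold_regression(high, L, M, const_fn(0.1)),
               "fewer than 3")
})

test_that("per-call FN weighting restores band-mixed counts", {
  # calls split across two FN bands; weights undo the planted thinning exactly
  tab <- fn_table(c(0, 0.10), c(0.10, 0.50), c(0.5, 0.2))
  maf <- c(rep(0.05, 10), rep(0.3, 10))
  calls <- het_calls("c1", seq_along(maf), "A", "G",
                     paste0("x", seq_along(maf)), round(maf * 1000), 1000)
  calls$MAF <- maf
  reg <- maf_threshold_regression(calls, L = 1e6, M = 1, fn_table = tab,
                                  alpha = 0, f_grid = seq(0.1, 0.5, 0.1))
  # weighted count at f = 0.5: 10/0.5 + 10/0.8
  expect_equal(reg$grid$rate[5], (10 / 0.5 + 10 / 0.8) / 1e6)
})

test_that("conversion-rate calibration scales with the heterozygosity window", {
  sfs <- sfs_summary(runif(2000, 0.01, 0.5), callable_bp = 1e6)
  expect_equal(conversion_rate_from_slope(0, sfs), 0)
  c1 <- conversion_rate_from_slope(1e-8, sfs)
  sfs2 <- sfs_summary(sfs$maf, callable_bp = sfs$callable_bp / 2)  # double Pi
  expect_equal(conversion_rate_from_slope(1e-8, sfs2), c1 / 2)
  flat <- sfs_summary(rep(0.05, 10), callable_bp = 1e6)
  expect_error(conversion_rate_from_slope(1e-8, flat), "flat")
})

test_that("bootstrap_se behaves like a bootstrap", {
  expect_equal(bootstrap_se(rep(5, 40), mean, B = 100), 0)
  set.seed(32)
  x <- rnorm(100, sd = 2)
  se <- bootstrap_se(x, mean, B = 1000)
  expect_lt(abs(se - 2 / sqrt(100)) / (2 / sqrt(100)), 0.15)
  set.seed(99); a <- bootstrap_se(x, mean, B = 200)
  set.seed(99); b <- bootstrap_se(x, mean, B = 200)
  expect_identical(a, b)
  expect_error(bootstrap_se(x, mean, B = 50), ">= 100")
  expect_error(bootstrap_se(x, function(z) stop("boom"), B = 100), "boom")
})

test_that("scaled-genome cohort with truth meioses recovers planted rates", {
  cfg <- cohort_config(n_individuals = 250, seed = 33)
  coh <- generate_cohort(cfg)
  est <- estimate_rates(coh$calls, coh$segments, coh$fn_table, alpha = 0.01,
                        sfs = coh$sfs, assignments = truth_assignments(coh),
                        B = 200)
  expect_lt(abs(est$mu_intercept - cfg$mu), 3 * est$se_mu_intercept)
  expect_lt(abs(est$mu_singleton - cfg$mu), 3 * est$se_mu_singleton)
  expect_lt(abs(est$conversion_rate - cfg$conversion_rate),
            3 * est$se_conversion_rate)
  expect_gt(est$slope, 0)
})

test_that("the estimate is insensitive to extra trimming but not to none", {
  cfg <- cohort_config(n_individuals = 200, seed = 34)
  coh <- generate_cohort(cfg)
  asg <- truth_assignments(coh)
  run <- function(trim) estimate_rates(coh$calls, coh$segments, coh$fn_table,
                                       alpha = 0.01, sfs = coh$sfs,
                                       assignments = asg, trim_bp = trim,
                                       B = 200)
  e2 <- run(2e6); e3 <- run(3e6); e0 <- run(0)
  # beyond the boundary-contamination scale: no systematic change
  expect_lt(abs(e2$mu_singleton - e3$mu_singleton),
            3 * sqrt(e2$se_mu_singleton^2 + e3$se_mu_singleton^2))
  # without trimming, boundary heterozygotes mimic conversions and inflate
  # the apparent conversion rate strongly
  expect_gt(e0$conversion_rate,
            e2$conversion_rate + 3 * e2$se_conversion_rate)
})

test_that("calls written as VCF read back identically", {
  cfg <- cohort_config(n_individuals = 25, seed = 35)
  coh <- generate_cohort(cfg)
  path <- tempfile(fileext = ".vcf")
  write_cohort_vcf(coh, path)
  back <- read_calls_vcf(path)
  orig <- coh$calls[order(coh$calls$chrom, coh$calls$pos), ]
  back <- back[order(back$chrom, back$pos), ]
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$pos, orig$pos)
  expect_equal(back$individual_id, orig$individual_id)
  expect_equal(back$AC, orig$AC)
  expect_equal(back$MAF, orig$MAF)
})
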