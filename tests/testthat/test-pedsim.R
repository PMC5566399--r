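# helpers for mosaic validity ------------------------------------------------

expect_valid_mosaic <- function(hap, len) {
  expect_true(all(diff(hap$br) > 0))
  expect_true(all(hap$br > 0 & hap$br < len))
  expect_length(hap$lab, length(hap$br) + 1L)
  if (length(hap$br))
    expect_true(all(hap$lab[-1] != hap$lab[-length(hap$lab)]))
}

test_that("cousin pedigrees carry 2k+4 meioses and consistent structure", {
  expect_identical(build_pedigree("first_cousin")$meioses, 6L)
  expect_identical(build_pedigree("second_cousin")$meioses, 8L)
  expect_identical(build_pedigree("third_cousin")$meioses, 10L)
  expect_identical(build_pedigree("fourth_cousin")$meioses, 12L)
  expect_error(build_pedigree("fifth_cousin"), "unsupported")
  ped <- build_pedigree("third_cousin")
  m <- ped$members
  nonfounder <- m[!m$founder, ]
  expect_true(all(nonfounder$father %in% m$id))
  expect_true(all(nonfounder$mother %in% m$id))
  expect_true(all(is.na(m$father[m$founder])))
})

test_that("gametes tile the genome with merged labels", {
  g <- genome_model(c("c1", "c2"), c(6e7, 4e7),
                    map_points = list(cbind(c(0, 1e7, 6e7), c(0, 50, 75)),
                                      cbind(c(0, 4e7), c(0, 50))))
  set.seed(1)
  parent <- founder_haplotypes(g, c(1L, 2L))
  for (r in 1:50) {
    gam <- simulate_gamete(parent, g)
    for (i in 1:2) expect_valid_mosaic(gam[[i]], g$length_bp[i])
  }
  # second-generation gamete from recombinant parents still tiles
  p2 <- list(simulate_gamete(parent, g), simulate_gamete(parent, g))
  for (r in 1:20) {
    gam <- simulate_gamete(p2, g)
    for (i in 1:2) expect_valid_mosaic(gam[[i]], g$length_bp[i])
  }
})

test_that("a 0 cM chromosome transmits one intact parental homolog, 50/50", {
  g <- genome_model("c1", 1e7, cm_total = 0)
  parent <- founder_haplotypes(g, c(7L, 9L))
  set.seed(2)
  labs <- replicate(400, simulate_gamete(parent, g)[[1]]$lab)
  expect_true(all(labs %in% c(7L, 9L)))
  expect_gt(mean(labs == 7L), 0.4)
  expect_lt(mean(labs == 7L), 0.6)
})

test_that("crossover counts are Poisson with mean = Morgans", {
  g <- genome_model("c1", 1e8, cm_total = 100)  # 1 Morgan
  parent <- founder_haplotypes(g)
  set.seed(3)
  n <- 20000
  # with two distinct constant parental labels every crossover is a breakpoint
  counts <- replicate(n, length(simulate_gamete(parent, g)[[1]]$br))
  expect_lt(abs(mean(counts) - 1), 3 / sqrt(n))     # mean 1 +- 3 SE
  expect_lt(abs(var(counts) - 1), 4 * sqrt(2 / n))  # Poisson variance 1
})

test_that("breakpoints are uniform in bp under a linear map", {
  g <- genome_model("c1", 1e8, cm_total = 200)
  parent <- founder_haplotypes(g)
  set.seed(4)
  brs <- unlist(replicate(4000, simulate_gamete(parent, g)[[1]]$br))
  ks <- suppressWarnings(stats::ks.test(brs / 1e8, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("breakpoints follow the genetic map density, not physical length", {
  # first 20% of the chromosome carries 80% of the cM
  mp <- list(cbind(c(0, 2e7, 1e8), c(0, 160, 200)))
  g <- genome_model("c1", 1e8, map_points = mp)
  parent <- founder_haplotypes(g)
  set.seed(5)
  brs <- unlist(replicate(3000, simulate_gamete(parent, g)[[1]]$br))
  frac <- mean(brs < 2e7)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / length(brs)))
})

test_that("unrelated parents never produce autozygosity", {
  g <- tiny_genome()
  ped <- build_pedigree("unrelated")
  set.seed(6)
  for (r in 1:20) expect_identical(nrow(simulate_autozygosity(ped, g)), 0L)
})

test_that("first-cousin offspring are autozygous over ~1/16 of the genome", {
  g <- tiny_genome(4, 100e6)
  ped <- build_pedigree("first_cousin")
  set.seed(7)
  n <- 600
  fr <- replicate(n, {
    s <- simulate_autozygosity(ped, g)
    sum(s$end - s$start)
  }) / sum(g$length_bp)
  se <- sd(fr) / sqrt(n)
  expect_lt(abs(mean(fr) - 1 / 16), 4 * se)
})

test_that("with crossovers suppressed autozygosity is whole-chromosome or absent", {
  g <- genome_model(c("c1", "c2"), c(2e7, 3e7), cm_total = c(0, 0))
  ped <- build_pedigree("second_cousin")
  set.seed(8)
  for (r in 1:60) {
    s <- simulate_autozygosity(ped, g)
    if (nrow(s)) {
      expect_true(all(s$start == 0))
      expect_equal(s$end, g$length_bp[match(s$chrom, g$chrom)])
    }
  }
})

test_that("autozygous segments are sorted, in-bounds and non-overlapping", {
  g <- tiny_genome()
  ped <- build_pedigree("first_cousin")
  set.seed(9)
  for (r in 1:40) {
    s <- simulate_autozygosity(ped, g)
    if (!nrow(s)) next
    expect_true(all(s$start >= 0))
    expect_true(all(s$end <= g$length_bp[match(s$chrom, g$chrom)]))
    expect_true(all(s$end > s$start))
    for (cc in unique(s$chrom)) {
      b <- s[s$chrom == cc, ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
})

test_that("segment_summary reduces a segment set to its three features", {
  s <- segment_set("chr1", c(0, 20e6, 40e6), c(12e6, 35e6, 48e6))
  expect_equal(segment_summary(s, min_len_bp = 10e6),
               c(longest_bp = 15e6, mean_bp = 13.5e6, count = 2))
  empty <- segment_set(character(0), numeric(0), numeric(0))
  expect_equal(segment_summary(empty),
               c(longest_bp = 0, mean_bp = 0, count = 0))
  expect_equal(unname(segment_summary(s, min_len_bp = 0)["count"]), 3)
  expect_error(segment_summary(s, min_len_bp = -1))
})

test_that("segment sets round-trip through BED with individual ids", {
  s <- segment_set(c("chr1", "chr1", "chr2"), c(0, 5e6, 1e6),
                   c(2e6, 9e6, 4e6), c("a", "b", "a"))
  path <- tempfile(fileext = ".bed")
  write_segments_bed(s, path)
  s2 <- read_segments_bed(path)
  expect_equal(s2$chrom, s$chrom)
  expect_equal(s2$start, s$start)
  expect_equal(s2$end, s$end)
  expect_equal(s2$individual_id, s$individual_id)
})

test_that("segment_set rejects malformed intervals", {
  expect_error(segment_set("chr1", 10, 10), "start < end")
  expect_error(segment_set("chr1", -1, 10), "start < end")
  expect_error(segment_set(c("chr1", "chr1"), c(0, 5), c(10, 15)), "overlap")
})
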