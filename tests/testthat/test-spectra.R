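test_that("context classification collapses strands onto pyrimidine classes", {
  expect_equal(classify_context("C", "C", "G", "T"), "CCG>CTG")
  # reverse-complement strand maps to the same class
  expect_equal(classify_context("C", "G", "G", "A"), "CCG>CTG")
  expect_equal(classify_context("T", "T", "A", "G"), "TTA>TGA")
  expect_error(classify_context("A", "C", "A", "C"), "differ")
  expect_error(classify_context("N", "C", "A", "T"), "invalid")
})

test_that("all 192 strand-explicit substitutions map 2-to-1 onto 96 classes", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(p5 = bases, ref = bases, p3 = bases, alt = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  # 64 triplets x 3 alternates = 192 strand-explicit substitutions
  expect_equal(nrow(combos), 192)
  cls <- classify_context(combos$p5, combos$ref, combos$p3, combos$alt)
  expect_setequal(cls, context_classes())
  expect_true(all(table(cls) == 2))
  expect_length(context_classes(), 96)
})

test_that("spectrum counts zero-fill all classes and reject unknowns", {
  s <- spectrum_counts(c("CCG>CTG", "CCG>CTG", "ACA>AGA"), label = "toy")
  expect_length(s, 96)
  expect_equal(sum(s), 3)
  expect_equal(unname(s["CCG>CTG"]), 2L)
  expect_error(spectrum_counts("CCG>AAA"), "unknown")
})

test_that("triplet composition is a 32-class frequency vector", {
  set.seed(40)
  ref <- synth_reference(30000, cpg_enrichment = 1)
  comp <- triplet_composition(ref)
  expect_length(comp, 32)
  expect_equal(sum(comp), 1)
  expect_true(all(substr(names(comp), 2, 2) %in% c("C", "T")))
  # CpG enrichment raises the frequency of CG-containing triplets
  set.seed(41)
  rich <- triplet_composition(synth_reference(30000, cpg_enrichment = 6))
  cg <- grepl("CG", names(comp))
  expect_gt(sum(rich[cg]), sum(comp[cg]))
})

test_that("composition normalization reweights and preserves totals", {
  classes <- context_classes()
  counts <- spectrum_counts(rep(c("ACA>AGA", "ACG>ATG", "TCG>TTG", "GTC>GGC"),
                                c(10, 10, 10, 10)),
                            composition = NULL)
  comp_src <- rep(1 / 32, 32)
  names(comp_src) <- sort(unique(canonical_triplet(
    apply(expand.grid(c("A","C","G","T"), c("C","T"), c("A","C","G","T")),
          1, paste, collapse = ""))))
  attr(counts, "composition") <- comp_src
  # identity when target equals source
  same <- normalize_composition(counts, comp_src)
  expect_equal(as.numeric(same), as.numeric(counts))
  # doubling one triplet's target frequency doubles its weight pre-rescale:
  # worked by hand for the 4-context toy
  comp_tgt <- comp_src
  comp_tgt["ACG"] <- comp_tgt["ACG"] * 2
  adj <- normalize_composition(counts, comp_tgt)
  expect_equal(sum(adj), sum(counts))  # total preserved
  # hand computation: weights (1,2,1,1) on equal counts of 10, rescaled by 40/50
  expect_equal(unname(adj["ACG>ATG"]), 10 * 2 * 40 / 50)
  expect_equal(unname(adj["ACA>AGA"]), 10 * 40 / 50)
  # zero source frequency with nonzero count is an error
  comp_bad <- comp_src; comp_bad["ACA"] <- 0
  attr(counts, "composition") <- comp_bad
  expect_error(normalize_composition(counts, comp_tgt), "zero source")
})

test_that("Yates 2x2 comparison matches the textbook formula and chisq.test", {
  r <- compare_context(10, 90, 10, 90)
  expect_equal(r$ratio, 1)
  expect_equal(r$chisq, 0)
  expect_gt(r$p, 0.99)
  # the published CCG>CTG table
  r2 <- compare_context(30, 1122, 120, 6828)
  expect_equal(round(r2$ratio, 3), 1.508)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(30, 1122, 120, 6828), 2, byrow = TRUE),
                      correct = TRUE))
  expect_equal(r2$chisq, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r2$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(r2$p_bonferroni, min(1, 96 * oracle$p.value))
  # swapping the rows inverts the ratio and keeps p
  r3 <- compare_context(120, 6828, 30, 1122)
  expect_equal(r3$ratio, 1 / r2$ratio)
  expect_equal(r3$p, r2$p)
  expect_error(compare_context(0, 0, 5, 5), "margins")
})

test_that("compare_spectra tests every context against the rest", {
  set.seed(42)
  a <- spectrum_counts(sample(context_classes(), 500, replace = TRUE))
  b <- spectrum_counts(sample(context_classes(), 800, replace = TRUE))
  tab <- compare_spectra(a, b)
  expect_equal(nrow(tab), 96)
  expect_equal(tab$a + tab$b, rep(500, 96))
  ok <- !is.na(tab$p)
  expect_true(all(tab$p[ok] >= 0 & tab$p[ok] <= 1))
  expect_true(all(tab$p_bonferroni[ok] >= tab$p[ok]))
})

test_that("Fisher combination reproduces frozen references", {
  expect_equal(combine_pvalues(c(1, 1)), 1)
  expect_equal(combine_pvalues(0.37), 0.37, tolerance = 1e-12)
  # frozen: pchisq(-2(log 0.0044 + log 0.019), df = 4, lower = FALSE)
  expect_equal(combine_pvalues(c(0.0044, 0.019)), 8.67e-4, tolerance = 1e-2)
  expect_lt(combine_pvalues(c(0.01, 0.01)), 0.01)
  # Stouffer alternative
  expect_equal(combine_pvalues(0.25, method = "stouffer"), 0.25,
               tolerance = 1e-12)
  expect_error(combine_pvalues(c(0, 0.5)), "lie in")
})

test_that("call contexts are read off a reference sequence", {
  ref <- Biostrings::DNAStringSet(c(c1 = "AACGTT"))
  calls <- het_calls(c("c1", "c1"), c(3, 4), c("C", "G"), c("T", "A"),
                     c("x", "y"), 1, 100)
  expect_equal(call_contexts(calls, ref),
               c(classify_context("A", "C", "G", "T"),
                 classify_context("C", "G", "T", "A")))
  bad <- het_calls("c1", 3, "G", "A", "x", 1, 100)  # wrong reference base
  expect_error(call_contexts(bad, ref), "mismatch")
  edge <- het_calls("c1", 1, "A", "G", "x", 1, 100)
  expect_error(call_contexts(edge, ref), "edge")
})
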