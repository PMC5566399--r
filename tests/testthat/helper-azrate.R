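# Shared fixtures and memoized heavy simulations.

.az_cache <- new.env(parent = emptyenv())

# 22-autosome training set shared by the classifier tests and the
# end-to-end recovery test; built once per session under a fixed seed.
full_training <- function() {
  if (is.null(.az_cache$training)) {
    set.seed(4711)
    .az_cache$training <- build_training(default_genome(), n_per_class = 2000)
  }
  .az_cache$training
}

# Held-out feature matrices per relationship class on the full map.
full_heldout <- function(n = 400) {
  if (is.null(.az_cache$heldout)) {
    set.seed(4712)
    rels <- c("first_cousin", "second_cousin", "third_cousin", "fourth_cousin")
    .az_cache$heldout <- lapply(stats::setNames(nm = rels), function(r)
      simulate_segment_features(r, default_genome(), n))
  }
  .az_cache$heldout
}

# Small two-chromosome genome for fast unit tests.
tiny_genome <- function(n_chrom = 2, chrom_bp = 80e6, cm_per_mb = 1.25) {
  scaled_genome(n_chrom, chrom_bp, cm_per_mb)
}

# Hard class assignments for a feature matrix.
hard_classes <- function(features, training) {
  apply(features, 1, function(x) classify_individual(x, training)$M_star)
}

# Truth-ledger meiosis assignments for a synthetic cohort (bypasses the
# classifier where a test targets the counting/regression machinery).
truth_assignments <- function(cohort, min_len_bp = 10e6) {
  truth <- cohort$ledger$individuals
  m <- stats::setNames(truth$meioses, truth$individual_id)
  segs <- cohort$segments
  ids <- unique(segs$individual_id)
  autoz <- vapply(ids, function(i) {
    s <- segs[segs$individual_id == i, ]
    len <- s$end - s$start
    sum(len[len >= min_len_bp])
  }, numeric(1))
  data.frame(individual_id = ids, M_star = as.numeric(m[ids]),
             M_post = as.numeric(m[ids]), autozygous_bp = autoz,
             uninformative = autoz == 0)
}
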