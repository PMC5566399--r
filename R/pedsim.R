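#' Cousin-type pedigrees
#'
#' Builds the pedigree joining the two homologous chromosome sets of the
#' offspring of k-th cousin parents through a single shared ancestral couple.
#' The offspring's two homologs are separated by `2k + 4` meioses: six for
#' first cousins, eight for second cousins, and so on. `"unrelated"` is
#' accepted for control simulations and carries no ancestral loop.
#'
#' @param relationship one of `"first_cousin"`, `"second_cousin"`,
#'   `"third_cousin"`, `"fourth_cousin"`, or `"unrelated"`.
#' @return An object of class `"pedigree"`: a list with `relationship`,
#'   cousin degree `k`, `meioses` (`NA` for unrelated parents) and a `members`
#'   data frame (`id`, `father`, `mother`, `sex`, `founder`).
#' @examples
#' build_pedigree("first_cousin")$meioses   # 6
#' build_pedigree("fourth_cousin")$meioses  # 12
#' @export
build_pedigree <- function(relationship) {
  supported <- c(first_cousin = 1L, second_cousin = 2L, third_cousin = 3L,
                 fourth_cousin = 4L)
  if (identical(relationship, "unrelated")) {
    members <- data.frame(
      id = c("P1", "P2", "O"), father = c(NA, NA, "P1"),
      mother = c(NA, NA, "P2"), sex = c("M", "F", "U"),
      founder = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
    return(structure(list(relationship = "unrelated", k = NA_integer_,
                          meioses = NA_integer_, members = members),
                     class = "pedigree"))
  }
  if (!relationship %in% names(supported))
    stop("unsupported relationship: ", relationship)
  k <- supported[[relationship]]

  # One ancestral couple (A, B); two sibling lineages of k generations down to
  # the focal offspring's parents; all married-in spouses are founders.
  ids <- c("A", "B")
  members <- list(
    data.frame(id = c("A", "B"), father = NA_character_,
               mother = NA_character_, sex = c("M", "F"),
               founder = TRUE, stringsAsFactors = FALSE))
  for (s in 1:2) {
    prev_f <- "A"; prev_m <- "B"
    for (j in seq_len(k + 1)) {
      cid <- sprintf("L%d_%d", s, j)
      sex <- if (j %% 2 == 1) "M" else "F"
      members[[length(members) + 1L]] <- data.frame(
        id = cid, father = prev_f, mother = prev_m, sex = sex,
        founder = FALSE, stringsAsFactors = FALSE)
      if (j <= k) {
        sid <- sprintf("S%d_%d", s, j)
        ssex <- if (sex == "M") "F" else "M"
        members[[length(members) + 1L]] <- data.frame(
          id = sid, father = NA_character_, mother = NA_character_,
          sex = ssex, founder = TRUE, stringsAsFactors = FALSE)
        if (sex == "M") { prev_f <- cid; prev_m <- sid }
        else            { prev_f <- sid; prev_m <- cid }
      }
    }
  }
  members[[length(members) + 1L]] <- data.frame(
    id = "O", father = sprintf("L%d_%d", 1, k + 1),
    mother = sprintf("L%d_%d", 2, k + 1), sex = "U", founder = FALSE,
    stringsAsFactors = FALSE)
  members <- do.call(rbind, members)
  structure(list(relationship = relationship, k = k,
                 meioses = 2L * k + 4L, members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %s (%s meioses, %d members)\n", x$relationship,
              ifelse(is.na(x$meioses), "NA", x$meioses), nrow(x$members)))
  invisible(x)
}

# A haplotype mosaic for one chromosome: internal breakpoints `br` (bp,
# strictly increasing, exclusive of 0 and the chromosome end) and integer
# founder-allele labels `lab` of length length(br) + 1.
.const_hap <- function(label) list(br = numeric(0), lab = as.integer(label))

# Sorted sample of n Uniform(0, max) values via exponential spacings
# (avoids a sort in the innermost simulation loop).
.sorted_runif <- function(n, max) {
  cs <- cumsum(stats::rexp(n + 1L))
  cs[seq_len(n)] / cs[n + 1L] * max
}

# Simulate one gamete on chromosome i of `genome` from a parent's two
# haplotype mosaics. Crossover count ~ Poisson(genetic length in Morgans),
# breakpoint positions uniform on the cM scale mapped to bp through the map
# inverse, starting haplotype chosen with probability 1/2. All randomness is
# drawn from the R RNG; the mosaic merge runs in C++. `bp_per_cm` is the
# linear-map fast path (NA for multi-point maps).
.gamete_chrom <- function(hap1, hap2, g_cm, bp_per_cm, genome, i) {
  first <- if (stats::runif(1) < 0.5) 1L else 2L
  n <- if (g_cm > 0) stats::rpois(1L, g_cm / 100) else 0L
  if (n == 0L)
    return(if (first == 1L) hap1 else hap2)
  cx_cm <- .sorted_runif(n, g_cm)
  cx <- if (is.na(bp_per_cm)) .cm_to_bp(genome, i, cx_cm)
        else cx_cm * bp_per_cm
  .cpp_gamete(hap1$br, hap1$lab, hap2$br, hap2$lab, cx, first)
}

# bp per cM for chromosomes with two-point (linear) maps, NA otherwise.
.linear_scale <- function(genome) {
  vapply(seq_along(genome$chrom), function(i) {
    m <- genome$map[[i]]
    if (nrow(m) == 2L && m[2L, 2L] > 0) m[2L, 1L] / m[2L, 2L] else NA_real_
  }, numeric(1))
}

#' Simulate a gamete from a parent
#'
#' Drops one meiosis: for each chromosome the crossover count is Poisson with
#' mean equal to the chromosome's genetic length in Morgans (Haldane model, no
#' interference), crossover positions are uniform on the genetic (cM) scale
#' and mapped to bp through the genetic map, and the starting parental
#' haplotype is chosen with probability 1/2.
#'
#' @param parent a list of two haplotype mosaics as returned by this function
#'   or [founder_haplotypes()]; each mosaic is a per-chromosome list with
#'   breakpoints `br` (bp) and integer labels `lab`.
#' @param genome a [genome_model()].
#' @return A haplotype mosaic (list over chromosomes).
#' @seealso [simulate_autozygosity()]
#' @export
simulate_gamete <- function(parent, genome) {
  stopifnot(length(parent) == 2L)
  scale <- .linear_scale(genome)
  lapply(seq_along(genome$chrom), function(i)
    .gamete_chrom(parent[[1L]][[i]], parent[[2L]][[i]],
                  genome$cm_total[i], scale[i], genome, i))
}

#' Founder haplotype pair with distinct labels
#'
#' @param genome a [genome_model()].
#' @param labels two distinct integer founder-allele labels.
#' @return A list of two constant haplotype mosaics spanning the genome.
#' @export
founder_haplotypes <- function(genome, labels = c(1L, 2L)) {
  stopifnot(length(labels) == 2L, labels[1] != labels[2])
  list(lapply(genome$chrom, function(x) .const_hap(labels[1])),
       lapply(genome$chrom, function(x) .const_hap(labels[2])))
}

# Maximal intervals on chromosome i where two mosaics carry the same label
# (possibly a 0-row matrix).
.autozygous_chrom <- function(h1, h2, len) {
  .cpp_equal_runs(h1$br, h1$lab, h2$br, h2$lab, len)
}

#' Simulate the autozygous segments of a pedigree's focal offspring
#'
#' Gene-drops gametes through a cousin-type pedigree: the ancestral couple's
#' four homologs carry distinct founder labels, every married-in founder
#' contributes its own private label, and the focal offspring's autozygous
#' segments are the maximal intervals where its two homologs carry the same
#' founder label.
#'
#' @param pedigree a [build_pedigree()] object.
#' @param genome a [genome_model()].
#' @param individual_id id recorded on the returned segments.
#' @return A data frame of class `"segment_set"` with columns `chrom`,
#'   `start`, `end` (0-based half-open bp) and `individual_id`; zero rows when
#'   the offspring carries no autozygous sequence.
#' @examples
#' g <- scaled_genome(2, 100e6)
#' set.seed(1)
#' segs <- simulate_autozygosity(build_pedigree("first_cousin"), g)
#' @export
simulate_autozygosity <- function(pedigree, genome, individual_id = "ind1") {
  stopifnot(inherits(pedigree, "pedigree"))
  if (identical(pedigree$relationship, "unrelated"))
    return(segment_set(character(0), numeric(0), numeric(0), individual_id))
  k <- pedigree$k
  scale <- .linear_scale(genome)
  cm_tot <- genome$cm_total
  len_bp <- genome$length_bp
  nchr <- length(genome$chrom)
  segs_by_chrom <- vector("list", nchr)
  h12 <- list(.const_hap(1L), .const_hap(2L))
  h34 <- list(.const_hap(3L), .const_hap(4L))
  for (i in seq_len(nchr)) {
    uid <- 5L
    side <- function() {
      # child of the ancestral couple, then k descents with founder spouses
      homs <- list(
        .gamete_chrom(h12[[1L]], h12[[2L]], cm_tot[i], scale[i], genome, i),
        .gamete_chrom(h34[[1L]], h34[[2L]], cm_tot[i], scale[i], genome, i))
      for (j in seq_len(k)) {
        g <- .gamete_chrom(homs[[1L]], homs[[2L]], cm_tot[i], scale[i],
                           genome, i)
        homs <- list(g, .const_hap(uid))
        uid <<- uid + 1L
      }
      .gamete_chrom(homs[[1L]], homs[[2L]], cm_tot[i], scale[i], genome, i)
    }
    top <- side(); bottom <- side()
    segs_by_chrom[[i]] <- .autozygous_chrom(top, bottom, len_bp[i])
  }
  nseg <- vapply(segs_by_chrom, nrow, integer(1))
  if (!sum(nseg))
    return(segment_set(character(0), numeric(0), numeric(0), individual_id))
  mat <- do.call(rbind, segs_by_chrom[nseg > 0L])
  segment_set(rep(genome$chrom[nseg > 0L], nseg[nseg > 0L]),
              mat[, "start"], mat[, "end"], individual_id)
}

#' Construct a segment set
#'
#' @param chrom,start,end segment coordinates (0-based half-open bp).
#' @param individual_id individual id(s), recycled.
#' @param annotation `"simulated"` or `"observed"`.
#' @return A data frame of class `"segment_set"` sorted by individual,
#'   chromosome and start, with non-overlap enforced per individual and
#'   chromosome.
#' @export
segment_set <- function(chrom, start, end, individual_id = "ind1",
                        annotation = "simulated") {
  n <- max(length(chrom), length(start))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   individual_id = rep_len(as.character(individual_id), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("segments must satisfy 0 <= start < end")
    df <- df[order(df$individual_id, df$chrom, df$start), , drop = FALSE]
    ov <- duplicated(df[, c("individual_id", "chrom")]) &
      c(FALSE, df$start[-1] < df$end[-nrow(df)])
    if (any(ov)) stop("segments overlap within an individual")
    rownames(df) <- NULL
  }
  structure(df, class = c("segment_set", "data.frame"),
            annotation = annotation)
}

#' Summary statistics of a segment-length distribution
#'
#' The three features used for meiosis-count inference: the longest segment,
#' the mean segment length and the number of segments, computed over segments
#' at least `min_len_bp` long.
#'
#' @param segments a [segment_set()] (single individual).
#' @param min_len_bp minimum segment length in bp (default 10 Mb, the
#'   threshold enriching for genuinely identical-by-descent segments).
#' @return Named numeric vector `(longest_bp, mean_bp, count)`; `(0, 0, 0)`
#'   for an empty (or fully filtered) segment set.
#' @examples
#' s <- segment_set("chr1", c(0, 20e6, 40e6), c(12e6, 35e6, 48e6))
#' segment_summary(s, min_len_bp = 10e6)
#' @export
segment_summary <- function(segments, min_len_bp = 10e6) {
  stopifnot(min_len_bp >= 0)
  len <- segments$end - segments$start
  len <- len[len >= min_len_bp]
  if (!length(len))
    return(c(longest_bp = 0, mean_bp = 0, count = 0))
  c(longest_bp = max(len), mean_bp = mean(len), count = length(len))
}

#' Simulate segment-summary features for many pedigrees
#'
#' Convenience wrapper running [simulate_autozygosity()] `n` times and
#' reducing each replicate to its [segment_summary()] features.
#'
#' @param relationship passed to [build_pedigree()].
#' @param genome a [genome_model()].
#' @param n number of replicate pedigrees.
#' @param min_len_bp feature cutoff, see [segment_summary()].
#' @return An `n` x 3 matrix with columns `longest_bp`, `mean_bp`, `count`.
#' @export
simulate_segment_features <- function(relationship, genome, n,
                                      min_len_bp = 10e6) {
  ped <- build_pedigree(relationship)
  out <- matrix(0, nrow = n, ncol = 3,
                dimnames = list(NULL, c("longest_bp", "mean_bp", "count")))
  for (r in seq_len(n))
    out[r, ] <- segment_summary(simulate_autozygosity(ped, genome),
                                min_len_bp = min_len_bp)
  out
}

#' Read / write segment sets as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal convention;
#' the individual id travels in the BED name column.
#'
#' @param segments a [segment_set()].
#' @param path file path.
#' @return `read_segments_bed()` returns a [segment_set()];
#'   `write_segments_bed()` invisibly returns `path`.
#' @export
write_segments_bed <- function(segments, path) {
  gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1, end = segments$end),
    name = segments$individual_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_segments_bed
#' @param annotation annotation recorded on the read segments.
#' @export
read_segments_bed <- function(path, annotation = "observed") {
  gr <- rtracklayer::import(path, format = "BED")
  ind <- if (!is.null(gr$name)) gr$name else "ind1"
  segment_set(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
              individual_id = ind, annotation = annotation)
}
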