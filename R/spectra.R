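.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 canonical trinucleotide mutation classes
#'
#' Single-base substitutions classified by the mutated base and its two
#' flanking bases, collapsed onto the pyrimidine strand (central reference C
#' or T), giving 6 substitution types x 16 flank combinations = 96 classes.
#' Class strings read `"<triplet>><mutated triplet>"`, e.g. `"CCG>CTG"`.
#'
#' @return Character vector of the 96 class labels, ordered by substitution
#'   type then 5' and 3' flank.
#' @export
context_classes <- function() {
  subs <- rbind(c("C", "A"), c("C", "G"), c("C", "T"),
                c("T", "A"), c("T", "C"), c("T", "G"))
  out <- character(0)
  for (s in seq_len(nrow(subs)))
    for (p5 in .BASES)
      for (p3 in .BASES)
        out <- c(out, paste0(p5, subs[s, 1], p3, ">", p5, subs[s, 2], p3))
  out
}

#' Classify a substitution into its trinucleotide context class
#'
#' If the reference base is a purine (A or G), the strand is flipped: all
#' four bases are complemented and the flanks swap, so each of the 192
#' strand-explicit substitutions maps onto exactly one of the 96
#' pyrimidine-strand classes (a 2-to-1 collapse).
#'
#' @param five_prime,ref,three_prime,alt single bases (vectorized).
#' @return Character vector of class labels as in [context_classes()].
#' @examples
#' classify_context("C", "C", "G", "T")  # "CCG>CTG"
#' classify_context("C", "G", "G", "A")  # same class, opposite strand
#' @export
classify_context <- function(five_prime, ref, three_prime, alt) {
  up <- function(x) toupper(as.character(x))
  five_prime <- up(five_prime); ref <- up(ref)
  three_prime <- up(three_prime); alt <- up(alt)
  n <- length(ref)
  if (!all(c(length(five_prime), length(three_prime), length(alt)) == n))
    stop("inputs must have equal length")
  ok <- five_prime %in% .BASES & ref %in% .BASES &
    three_prime %in% .BASES & alt %in% .BASES
  if (!all(ok)) stop("invalid base(s)")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  p5 <- ifelse(flip, .COMP[three_prime], five_prime)
  p3 <- ifelse(flip, .COMP[five_prime], three_prime)
  r <- ifelse(flip, .COMP[ref], ref)
  a <- ifelse(flip, .COMP[alt], alt)
  paste0(p5, r, p3, ">", p5, a, p3)
}

#' Spectrum counts over the 96 context classes
#'
#' @param contexts character vector of class labels (from
#'   [classify_context()]).
#' @param label dataset label.
#' @param composition optional triplet-composition table (see
#'   [triplet_composition()]) of the dataset's callable region.
#' @return Named integer vector of class `"spectrum_counts"` over all 96
#'   classes (zero-filled), with attributes `label` and `composition`.
#' @export
spectrum_counts <- function(contexts, label = "spectrum",
                            composition = NULL) {
  classes <- context_classes()
  bad <- !contexts %in% classes
  if (any(bad)) stop("unknown context class: ", contexts[which(bad)[1]])
  counts <- table(factor(contexts, levels = classes))
  structure(stats::setNames(as.integer(counts), classes),
            label = label, composition = composition,
            class = "spectrum_counts")
}

#' Canonical (pyrimidine-strand) form of a triplet
#'
#' @param triplet character vector of trinucleotides.
#' @return The triplet itself when its central base is C or T, otherwise its
#'   reverse complement; 32 canonical triplets in total.
#' @export
canonical_triplet <- function(triplet) {
  triplet <- toupper(triplet)
  mid <- substr(triplet, 2, 2)
  flip <- mid %in% c("A", "G")
  rc <- vapply(strsplit(triplet[flip], ""), function(b)
    paste0(.COMP[b[3]], .COMP[b[2]], .COMP[b[1]]), character(1))
  triplet[flip] <- rc
  triplet
}

#' Triplet composition of a reference region
#'
#' Frequencies of the 32 canonical (strand-collapsed) trinucleotides in a
#' DNA sequence set, used to normalize spectra between datasets whose
#' callable regions differ in sequence composition (e.g. exomes versus whole
#' genomes).
#'
#' @param seqs a [Biostrings::DNAStringSet] (or object coercible to one).
#' @return Named numeric vector of 32 frequencies summing to 1.
#' @export
triplet_composition <- function(seqs) {
  seqs <- Biostrings::DNAStringSet(seqs)
  tf <- colSums(Biostrings::trinucleotideFrequency(seqs))
  keep <- !grepl("[^ACGT]", names(tf))
  tf <- tf[keep]
  canon <- canonical_triplet(names(tf))
  agg <- tapply(tf, canon, sum)
  out <- as.numeric(agg) / sum(agg)
  stats::setNames(out, names(agg))
}

#' Normalize a spectrum for composition differences
#'
#' Reweights each context count by the ratio of the target to the source
#' frequency of its central canonical triplet, then rescales so the total
#' count is preserved.
#'
#' @param counts a [spectrum_counts()] vector carrying a `composition`
#'   attribute (the source composition).
#' @param target_composition the composition to normalize to (named vector
#'   over the 32 canonical triplets).
#' @return A `spectrum_counts` vector (non-integer counts) with the target
#'   composition attached.
#' @export
normalize_composition <- function(counts, target_composition) {
  source_composition <- attr(counts, "composition")
  if (is.null(source_composition))
    stop("'counts' carries no composition table")
  trip <- substr(names(counts), 1, 3)
  src <- source_composition[trip]
  tgt <- target_composition[trip]
  if (any(is.na(src) | is.na(tgt)))
    stop("composition tables must cover all 32 canonical triplets")
  if (any(src == 0 & counts > 0))
    stop("zero source frequency for a triplet with nonzero counts")
  w <- ifelse(src > 0, tgt / src, 0)
  adj <- as.numeric(counts) * w
  tot <- sum(counts)
  if (sum(adj) > 0) adj <- adj * tot / sum(adj)
  structure(stats::setNames(adj, names(counts)),
            label = attr(counts, "label"), composition = target_composition,
            class = "spectrum_counts")
}

#' Compare one context's proportion between two mutation sets
#'
#' Tests, with a Yates-corrected chi-square on the 2x2 table
#' `rbind(c(a, b), c(c, d))` (`a`/`c` = counts in the context, `b`/`d` =
#' counts in all other contexts, per dataset), whether the proportion of
#' mutations falling in the context differs between two datasets. The
#' returned p-value is Bonferroni-adjusted for the 96 contexts tested.
#'
#' @param a,b,c,d the 2x2 table cells.
#' @param context optional context label carried through.
#' @return A list of class `"context_comparison"`: `context`, `table`,
#'   `ratio` (proportion in set 1 / proportion in set 2), `chisq`, `p`,
#'   `p_bonferroni`.
#' @examples
#' compare_context(30, 1122, 120, 6828)
#' @export
compare_context <- function(a, b, c, d, context = NA_character_) {
  if ((a + b) <= 0 || (c + d) <= 0 || (a + c) <= 0 || (b + d) <= 0)
    stop("all table margins must be positive")
  n <- a + b + c + d
  delta <- abs(a * d - b * c)
  chisq <- n * (max(delta - n / 2, 0))^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  ratio <- (a / (a + b)) / (c / (c + d))
  structure(list(context = context, table = matrix(c(a, b, c, d), 2,
                                                   byrow = TRUE),
                 ratio = ratio, chisq = chisq, p = p,
                 p_bonferroni = min(1, 96 * p)),
            class = "context_comparison")
}

#' @export
print.context_comparison <- function(x, ...) {
  cat(sprintf("context %s: ratio %.3f, chisq %.3f, p %.3g (Bonferroni %.3g)\n",
              ifelse(is.na(x$context), "?", x$context), x$ratio, x$chisq,
              x$p, x$p_bonferroni))
  invisible(x)
}

#' Compare all 96 contexts between two spectra
#'
#' @param counts_a,counts_b two [spectrum_counts()] vectors.
#' @return Data frame with one row per context: counts, ratio, chisq, `p`,
#'   `p_bonferroni`.
#' @export
compare_spectra <- function(counts_a, counts_b) {
  classes <- context_classes()
  ta <- sum(counts_a); tb <- sum(counts_b)
  rows <- lapply(classes, function(cl) {
    a <- as.numeric(counts_a[cl]); cc <- as.numeric(counts_b[cl])
    if (a + cc == 0)
      return(data.frame(context = cl, a = a, b = ta - a, c = cc, d = tb - cc,
                        ratio = NA, chisq = NA, p = NA, p_bonferroni = NA))
    r <- compare_context(a, ta - a, cc, tb - cc, context = cl)
    data.frame(context = cl, a = a, b = ta - a, c = cc, d = tb - cc,
               ratio = r$ratio, chisq = r$chisq, p = r$p,
               p_bonferroni = r$p_bonferroni)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine independent p-values
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"fisher"` (default): `-2 sum(log p)` against chi-square
#'   with `2k` df; `"stouffer"`: sum of normal scores over `sqrt(k)`.
#' @return Combined p-value.
#' @examples
#' combine_pvalues(c(0.0044, 0.019))  # ~8.6e-4
#' @export
combine_pvalues <- function(p, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (method == "fisher") {
    stat <- -2 * sum(log(p))
    stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  } else {
    z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
    stats::pnorm(z, lower.tail = FALSE)
  }
}

#' Trinucleotide context of calls against a reference
#'
#' @param calls a [het_calls()] table.
#' @param reference a named [Biostrings::DNAStringSet] covering the call
#'   chromosomes (1-based positions).
#' @return Character vector of context classes for the calls.
#' @export
call_contexts <- function(calls, reference) {
  reference <- Biostrings::DNAStringSet(reference)
  vapply(seq_len(nrow(calls)), function(i) {
    seq <- reference[[calls$chrom[i]]]
    pos <- calls$pos[i]
    if (pos < 2 || pos > length(seq) - 1)
      stop("call at a chromosome edge has no flanking context")
    trip <- as.character(Biostrings::subseq(seq, pos - 1, pos + 1))
    b <- strsplit(trip, "")[[1]]
    if (b[2] != calls$ref[i])
      stop("reference base mismatch at ", calls$chrom[i], ":", pos)
    classify_context(b[1], b[2], b[3], calls$alt[i])
  }, character(1))
}
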