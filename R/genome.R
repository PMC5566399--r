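#' Genome models: physical and genetic coordinates
#'
#' A genome model carries, for each autosome, its physical length in bp and a
#' monotone genetic map given as map points `(position_bp, cumulative_cM)`.
#' Crossover simulation draws breakpoints uniformly on the cM scale and maps
#' them back to bp by inverting this table, so any (piecewise-linear)
#' recombination map can be plugged in.
#'
#' All internal coordinates are 0-based, half-open `[start, end)` bp.
#'
#' @param chrom character vector of chromosome names.
#' @param length_bp physical chromosome lengths (bp), all `> 0`.
#' @param map_points a list (one element per chromosome) of two-column
#'   matrices/data.frames with columns `pos_bp` and `cm`. The first point must
#'   be `(0, 0)` and the last must lie at `length_bp`; `cm` must be
#'   non-decreasing. If `NULL`, a linear map is built from `cm_total`.
#' @param cm_total genetic lengths in cM, used when `map_points` is `NULL`.
#' @return An object of class `"genome_model"`: a list with elements `chrom`,
#'   `length_bp`, `cm_total` and `map` (per-chromosome map-point matrices).
#' @examples
#' g <- genome_model("chrA", 1e8, cm_total = 120)
#' genetic_length(g)
#' @export
genome_model <- function(chrom, length_bp, map_points = NULL, cm_total = NULL) {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (length(chrom) != length(length_bp))
    stop("'chrom' and 'length_bp' must have the same length")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("all chromosome lengths must be positive")
  if (is.null(map_points)) {
    if (is.null(cm_total))
      stop("supply either 'map_points' or 'cm_total'")
    cm_total <- as.numeric(cm_total)
    if (length(cm_total) != length(chrom) || any(cm_total < 0))
      stop("'cm_total' must be non-negative and match 'chrom'")
    map_points <- lapply(seq_along(chrom), function(i) {
      cbind(pos_bp = c(0, length_bp[i]), cm = c(0, cm_total[i]))
    })
  } else {
    if (length(map_points) != length(chrom))
      stop("'map_points' must have one element per chromosome")
    map_points <- lapply(seq_along(chrom), function(i) {
      m <- map_points[[i]]
      m <- cbind(pos_bp = as.numeric(m[, 1]), cm = as.numeric(m[, 2]))
      if (nrow(m) < 2 || m[1, "pos_bp"] != 0 || m[1, "cm"] != 0)
        stop("map for ", chrom[i], " must start at (0 bp, 0 cM)")
      if (abs(m[nrow(m), "pos_bp"] - length_bp[i]) > 0.5)
        stop("map for ", chrom[i], " must end at the chromosome length")
      if (is.unsorted(m[, "pos_bp"], strictly = TRUE))
        stop("map positions for ", chrom[i], " must be strictly increasing")
      if (is.unsorted(m[, "cm"]))
        stop("cumulative cM for ", chrom[i], " must be non-decreasing")
      m
    })
    cm_total <- vapply(map_points, function(m) m[nrow(m), "cm"], numeric(1))
  }
  structure(
    list(chrom = chrom, length_bp = length_bp, cm_total = cm_total,
         map = map_points),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.3g bp, %.1f cM\n",
              length(x$chrom), sum(x$length_bp), sum(x$cm_total)))
  invisible(x)
}

#' Total genetic length of a genome model
#'
#' @param genome a [genome_model()].
#' @return Genetic length in Morgans.
#' @export
genetic_length <- function(genome) sum(genome$cm_total) / 100

# GRCh37 autosome physical lengths and sex-averaged genetic lengths.
# cM values follow standard sex-averaged per-chromosome totals, scaled to a
# genome total of ~3590 cM (35.9 Morgans).
.grch37_autosomes <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length_bp = c(249250621, 243199373, 198022430, 191154276, 180915260,
                  171115067, 159138663, 146364022, 141213431, 135534747,
                  135006516, 133851895, 115169878, 107349540, 102531392,
                  90354753, 81195210, 78077248, 59128983, 63025520,
                  48129895, 51304566),
    cm = c(287.7, 272.8, 226.2, 217.3, 206.8, 194.5, 189.7, 170.2, 168.6,
           183.5, 160.3, 177.0, 127.5, 122.4, 143.8, 135.8, 130.2, 119.0,
           108.4, 109.7, 63.6, 75.1)
  )
}

#' Bundled human autosome map (GRCh37, sex-averaged)
#'
#' A deterministic 22-autosome genome model with GRCh37 physical lengths and a
#' linear sex-averaged genetic map per chromosome totalling ~35.9 Morgans.
#' This is the default arena for pedigree recombination simulation.
#'
#' @return A [genome_model()] with 22 autosomes.
#' @examples
#' g <- default_genome()
#' round(genetic_length(g), 2)
#' @export
default_genome <- function() {
  tab <- .grch37_autosomes()
  genome_model(tab$chrom, tab$length_bp, cm_total = tab$cm)
}

#' Scaled-down genome for desk-scale simulation
#'
#' A small genome preserving human-like recombination density (default
#' 1.25 cM/Mb), used by the synthetic-cohort generator and in tests where the
#' full 22-autosome map would be unnecessarily expensive.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_bp physical length of each chromosome (bp).
#' @param cm_per_mb recombination density in cM per Mb.
#' @return A [genome_model()].
#' @export
scaled_genome <- function(n_chrom = 4, chrom_bp = 150e6, cm_per_mb = 1.25) {
  genome_model(paste0("chr", seq_len(n_chrom)),
               rep(chrom_bp, n_chrom),
               cm_total = rep(chrom_bp / 1e6 * cm_per_mb, n_chrom))
}

# Map a vector of cM positions to bp on chromosome i (inverse of the map).
# Linear two-point maps take a fast closed form; general maps interpolate.
.cm_to_bp <- function(genome, i, cm) {
  m <- genome$map[[i]]
  if (nrow(m) == 2L)
    return(cm / m[2L, 2L] * m[2L, 1L])
  stats::approx(x = m[, "cm"], y = m[, "pos_bp"], xout = cm,
                ties = "ordered")$y
}

# Forward map: bp -> cumulative cM on chromosome i.
.bp_to_cm <- function(genome, i, bp) {
  m <- genome$map[[i]]
  if (nrow(m) == 2L)
    return(bp / m[2L, 1L] * m[2L, 2L])
  stats::approx(x = m[, "pos_bp"], y = m[, "cm"], xout = bp,
                ties = "ordered")$y
}

#' Read / write a genetic map as TSV
#'
#' The on-disk format is a tab-separated table with columns
#' `chrom`, `pos_bp`, `cm` (cumulative cM), one block of rows per chromosome,
#' first row of each block at `(0, 0)` and last row at the chromosome length.
#'
#' @param path file path.
#' @return `read_genetic_map()` returns a [genome_model()];
#'   `write_genetic_map()` invisibly returns `path`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "cm")
  if (!all(need %in% names(tab)))
    stop("genetic map TSV needs columns: ", paste(need, collapse = ", "))
  chroms <- unique(tab$chrom)
  maps <- lapply(chroms, function(cc) {
    b <- tab[tab$chrom == cc, , drop = FALSE]
    cbind(pos_bp = b$pos_bp, cm = b$cm)
  })
  len <- vapply(maps, function(m) m[nrow(m), "pos_bp"], numeric(1))
  genome_model(chroms, len, map_points = maps)
}

#' @rdname read_genetic_map
#' @param genome a [genome_model()] to serialize.
#' @export
write_genetic_map <- function(genome, path) {
  rows <- do.call(rbind, lapply(seq_along(genome$chrom), function(i) {
    m <- genome$map[[i]]
    data.frame(chrom = genome$chrom[i], pos_bp = m[, "pos_bp"], cm = m[, "cm"])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
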