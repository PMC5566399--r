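#' Simulate a training distribution for meiosis-count inference
#'
#' For each degree of parental relatedness (first to fourth cousins),
#' simulates `n_per_class` pedigrees with [simulate_autozygosity()] and
#' reduces each replicate to the three [segment_summary()] features computed
#' over segments at least `min_len_bp` long: longest segment, mean segment
#' length and segment count. Features are standardized with pooled
#' mean/SD over all training rows.
#'
#' @param genome a [genome_model()].
#' @param n_per_class simulated pedigrees per relationship class.
#' @param min_len_bp segment-length cutoff for the features (default 10 Mb).
#' @param relationships relationship classes to train on.
#' @param h kernel bandwidth of the classifier on the standardized feature
#'   scale (see [classify_individual()]).
#' @return An object of class `"meiosis_training"`: list with `features`
#'   (data frame: `meioses`, `longest_bp`, `mean_bp`, `count`), `centroids`
#'   (class-by-feature matrix on the standardized scale), `center`, `scale`
#'   (pooled standardization constants), `min_len_bp` and `h`.
#' @examples
#' \donttest{
#' tr <- build_training(scaled_genome(), n_per_class = 200)
#' }
#' @export
build_training <- function(genome, n_per_class,
                           min_len_bp = 10e6,
                           relationships = c("first_cousin", "second_cousin",
                                             "third_cousin", "fourth_cousin"),
                           h = 0.8) {
  stopifnot(n_per_class >= 1)
  feats <- lapply(relationships, function(rel)
    simulate_segment_features(rel, genome, n_per_class, min_len_bp))
  meioses <- vapply(relationships, function(rel)
    build_pedigree(rel)$meioses, integer(1))
  x <- do.call(rbind, feats)
  df <- data.frame(meioses = rep(meioses, each = n_per_class), x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  centroids <- do.call(rbind, lapply(seq_along(relationships), function(j) {
    colMeans(z[df$meioses == meioses[j], , drop = FALSE])
  }))
  rownames(centroids) <- as.character(meioses)
  structure(list(features = df, centroids = centroids, center = center,
                 scale = scale, min_len_bp = min_len_bp, h = h,
                 meioses = unname(meioses)),
            class = "meiosis_training")
}

#' @export
print.meiosis_training <- function(x, ...) {
  cat(sprintf("meiosis_training: %d rows, classes M = %s, h = %g\n",
              nrow(x$features), paste(x$meioses, collapse = "/"), x$h))
  invisible(x)
}

#' Read / write a training feature cache as TSV
#'
#' @param training a [build_training()] object.
#' @param path file path.
#' @return `read_training_tsv()` returns a `"meiosis_training"` object
#'   rebuilt from the cached rows.
#' @export
write_training_tsv <- function(training, path) {
  utils::write.table(training$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_tsv
#' @param min_len_bp,h see [build_training()].
#' @export
read_training_tsv <- function(path, min_len_bp = 10e6, h = 0.8) {
  df <- utils::read.delim(path)
  need <- c("meioses", "longest_bp", "mean_bp", "count")
  if (!all(need %in% names(df)))
    stop("training TSV needs columns: ", paste(need, collapse = ", "))
  x <- as.matrix(df[, need[-1]])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  meioses <- sort(unique(df$meioses))
  centroids <- do.call(rbind, lapply(meioses, function(m)
    colMeans(z[df$meioses == m, , drop = FALSE])))
  rownames(centroids) <- as.character(meioses)
  structure(list(features = df, centroids = centroids, center = center,
                 scale = scale, min_len_bp = min_len_bp, h = h,
                 meioses = meioses),
            class = "meiosis_training")
}

#' Infer the number of separating meioses for one individual
#'
#' Gaussian-kernel nearest-centroid classifier on the standardized
#' segment-summary features: class `M` receives weight proportional to
#' `exp(-||z - centroid_M||^2 / (2 h^2))`, normalized over classes (computed
#' via log-sum-exp, so distant points remain well-defined). The point
#' estimate is the class of maximal weight; ties break toward the smaller
#' `M` (the more recent common ancestor, conservative for the mutation
#' rate). An individual with no segment above the training cutoff is flagged
#' uninformative: it is still assigned weights (its feature vector is
#' `(0, 0, 0)`, typical of distant relatedness) but is excluded from the
#' cohort mean by [weighted_mean_meioses()].
#'
#' @param features either a [segment_set()] for one individual or a numeric
#'   vector `(longest_bp, mean_bp, count)`.
#' @param training a [build_training()] object.
#' @return A one-row data frame of class `"meiosis_assignment"`: columns
#'   `individual_id`, one weight column `w<M>` per class, `M_star`,
#'   `M_post` (posterior mean), `autozygous_bp` (total length of qualifying
#'   segments, the weighting mass) and `uninformative`.
#' @export
classify_individual <- function(features, training) {
  stopifnot(inherits(training, "meiosis_training"))
  id <- "ind1"
  autoz <- NA_real_
  if (inherits(features, "segment_set") || is.data.frame(features)) {
    id <- if (nrow(features)) features$individual_id[1] else "ind1"
    len <- features$end - features$start
    autoz <- sum(len[len >= training$min_len_bp])
    features <- segment_summary(features, min_len_bp = training$min_len_bp)
  }
  x <- as.numeric(features)[1:3]
  if (is.na(autoz)) autoz <- x[1] * 0 + x[2] * x[3]  # mean * count
  z <- (x - training$center) / training$scale
  d2 <- rowSums(sweep(training$centroids, 2, z)^2)
  logw <- -0.5 * d2 / training$h^2
  logw <- logw - max(logw)
  w <- exp(logw); w <- w / sum(w)
  meioses <- training$meioses
  star <- meioses[which.max(w)]  # which.max takes the first (smallest M) tie
  out <- data.frame(individual_id = id, t(w), M_star = star,
                    M_post = sum(w * meioses), autozygous_bp = autoz,
                    uninformative = x[3] == 0)
  names(out)[2:(1 + length(meioses))] <- paste0("w", meioses)
  class(out) <- c("meiosis_assignment", "data.frame")
  out
}

#' Classify every individual of a cohort
#'
#' @param segments a [segment_set()] with one or more individuals.
#' @param training a [build_training()] object.
#' @return A data frame with one [classify_individual()] row per individual.
#' @export
classify_cohort <- function(segments, training) {
  ids <- unique(segments$individual_id)
  rows <- lapply(ids, function(i)
    classify_individual(segments[segments$individual_id == i, , drop = FALSE],
                        training))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length-weighted cohort mean of the separating meioses
#'
#' Averages the per-individual meiosis estimate, weighting each individual by
#' the length of its (qualifying) autozygous genome, so that the mean matches
#' the per-base-pair mutational opportunity. Uninformative assignments are
#' skipped.
#'
#' @param assignments data frame from [classify_cohort()] (or rbind of
#'   [classify_individual()] rows).
#' @param estimate `"posterior"` (default) averages each individual's
#'   posterior mean meioses, propagating assignment uncertainty; `"point"`
#'   uses the hard assignments `M_star`.
#' @return The weighted mean number of separating meioses (scalar).
#' @examples
#' a <- data.frame(individual_id = c("a", "b"), M_star = c(6, 8),
#'                 M_post = c(6, 8), autozygous_bp = c(1e7, 1e7),
#'                 uninformative = FALSE)
#' weighted_mean_meioses(a)  # 7
#' @export
weighted_mean_meioses <- function(assignments,
                                  estimate = c("posterior", "point")) {
  estimate <- match.arg(estimate)
  keep <- !assignments$uninformative & assignments$autozygous_bp > 0
  if (!any(keep))
    stop("no informative assignments: no individual has a qualifying segment")
  a <- assignments[keep, , drop = FALSE]
  m <- if (estimate == "posterior") a$M_post else a$M_star
  sum(a$autozygous_bp * m) / sum(a$autozygous_bp)
}
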