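#' Average expression per timepoint
#'
#' Entry (g, t) is the arithmetic mean of gene g over the samples
#' available at time t (7 animals at 6 h under the default design,
#' 8 elsewhere).
#'
#' @param exprs genes x samples matrix or a
#'   \linkS4class{StrokeTimecourseExperiment}.
#' @param sample_sheet sample sheet (ignored when \code{exprs} is an
#'   experiment object).
#' @return genes x timepoints matrix, columns named by hour.
#' @export
averageProfiles <- function(exprs, sample_sheet = NULL) {
  if (is(exprs, "StrokeTimecourseExperiment")) {
    sample_sheet <- sampleSheet(exprs)
    exprs <- exprsMatrix(exprs)
  }
  tp <- sort(unique(sample_sheet$time_h))
  prof <- matrix(NA_real_, nrow(exprs), length(tp),
                 dimnames = list(rownames(exprs), tp))
  for (i in seq_along(tp)) {
    cols <- sample_sheet$sample_id[sample_sheet$time_h == tp[i]]
    cols <- intersect(cols, colnames(exprs))
    if (!length(cols)) stop("no samples at timepoint ", tp[i], " h")
    prof[, i] <- rowMeans(exprs[, cols, drop = FALSE], na.rm = TRUE)
  }
  prof
}

#' Mean-center and rank-standardize temporal profiles
#'
#' Mean-centering removes per-gene expression magnitude so clusters group
#' by shape; rank z-scores (average ranks for ties, then centered and
#' scaled to unit variance) place profiles in a space where squared
#' Euclidean distance is proportional to the Spearman correlation
#' distance, so ordinary K-means respects the rank-based metric.
#'
#' @param profiles genes x timepoints matrix from
#'   \code{\link{averageProfiles}}.
#' @return list with \code{centered} (mean-centered profiles),
#'   \code{rank_z} (rank z-scores; NA rows for degenerate profiles) and
#'   \code{degenerate} (logical flag for all-tied profiles).
#' @export
standardizeProfiles <- function(profiles) {
  if (ncol(profiles) < 2) stop("need at least 2 timepoints")
  centered <- profiles - rowMeans(profiles)
  ranks <- t(apply(profiles, 1, rank, ties.method = "average"))
  rsd <- apply(ranks, 1, sd)
  degenerate <- rsd == 0
  rank_z <- (ranks - rowMeans(ranks)) / rsd
  rank_z[degenerate, ] <- NA_real_
  list(centered = centered, rank_z = rank_z, degenerate = degenerate)
}

#' Spearman correlation distance between two profiles
#'
#' 1 minus the Spearman rank correlation; 0 for any strictly monotone
#' transform of the same ordering, 2 for perfectly reversed orderings.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return distance in [0, 2].
#' @export
spearmanDistance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman distance undefined for a constant vector")
  1 - cor(x, y, method = "spearman")
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the centers chosen so far
.kmeansppInit <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K == 1) return(centers)
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (k in 2:K) {
    if (sum(d2) <= 0)
      stop("fewer than K distinct profiles to seed centers from")
    centers[k, ] <- x[sample.int(n, 1, prob = d2 / sum(d2)), ]
    d2 <- pmin(d2, colSums((t(x) - centers[k, ])^2))
  }
  centers
}

#' K-means clustering of rank-standardized profiles
#'
#' Runs Euclidean K-means in rank z-score space (where squared distance is
#' proportional to Spearman distance), keeping the best of \code{n_init}
#' k-means++-seeded restarts by total within-cluster sum of squares. Degenerate
#' (all-tied) profiles are excluded from clustering and reported as NA.
#' Each cluster centroid is classified into a temporal archetype.
#'
#' @param standardized output of \code{\link{standardizeProfiles}} (or a
#'   genes x timepoints rank-z matrix).
#' @param K number of clusters (default 25, the number of patterns the
#'   analysis distinguishes).
#' @param seed integer seed making the restarts reproducible.
#' @param n_init number of random restarts (default 50).
#' @param timepoints_h timepoints of the profile columns.
#' @return A \linkS4class{ClusterResult}.
#' @export
clusterProfiles <- function(standardized, K = 25L, seed = 1L,
                            n_init = 50L,
                            timepoints_h = c(0, 1, 2, 3, 6, 24)) {
  rz <- if (is.list(standardized)) standardized$rank_z else standardized
  ok <- rowSums(is.na(rz)) == 0
  x <- rz[ok, , drop = FALSE]
  if (K < 1) stop("K must be >= 1")
  if (nrow(x) < K)
    stop("K = ", K, " exceeds the ", nrow(x), " clusterable profiles")
  set.seed(as.integer(seed))
  km <- NULL
  for (i in seq_len(n_init)) {
    centers <- .kmeansppInit(x, K)
    cand <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 100L))
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  cl <- rep(NA_integer_, nrow(rz))
  cl[ok] <- km$cluster
  names(cl) <- rownames(rz)
  arch <- apply(km$centers, 1, function(ctr)
    classifyArchetype(ctr - mean(ctr), timepoints_h))
  new("ClusterResult", K = as.integer(K), cluster = cl,
      centers = km$centers, inertia = km$tot.withinss,
      seed = as.integer(seed), n_init = as.integer(n_init),
      archetype = unname(arch))
}
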