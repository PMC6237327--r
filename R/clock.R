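#' Select a shape-diverse clock panel
#'
#' Takes the top \code{k_per_archetype} genes (by significance rank) from
#' every archetype present, so the panel combines temporally overlapping
#' but distinct profiles - the property that lets a gene panel pin down
#' elapsed time.
#'
#' @param ranked ranking data.frame (\code{gene_id}, \code{rank}) from
#'   \code{\link{rankAndThreshold}}.
#' @param archetypes named character vector gene -> archetype label
#'   (ground truth or cluster-derived); genes labeled \code{"NULL"} or
#'   \code{"OTHER"} are ignored.
#' @param k_per_archetype genes to take per archetype (default 3).
#' @return character vector of panel gene IDs.
#' @export
selectPanel <- function(ranked, archetypes, k_per_archetype = 3L) {
  labs <- archetypes[!archetypes %in% c("NULL", "OTHER")]
  if (!length(labs)) stop("no archetype-labeled genes to select from")
  pos <- match(names(labs), ranked$gene_id)
  ord <- ranked$rank[pos]
  panel <- unlist(lapply(sort(unique(labs)), function(a) {
    g <- names(labs)[labs == a]
    g <- g[order(ord[match(g, names(labs))])]
    if (length(g) < k_per_archetype)
      warning("archetype ", a, " has only ", length(g), " genes")
    utils::head(g, k_per_archetype)
  }), use.names = FALSE)
  panel
}

#' Train a stroke-clock model
#'
#' For each panel gene, stores the mean and SD of its raw values across
#' all training samples and the per-timepoint mean of its standardized
#' values (the centroid curve). A new sample is later standardized with
#' these same training statistics, so a single sample can be placed on
#' the curves without self-normalization.
#'
#' @param ste training data: a \linkS4class{StrokeTimecourseExperiment}.
#' @param panel character vector of panel gene IDs.
#' @param grid_step grid resolution in hours for estimation (default
#'   0.1).
#' @param tau_w therapeutic-window threshold in hours (default 4.5, the
#'   thrombolysis window).
#' @return A \linkS4class{ClockModel}.
#' @export
trainClock <- function(ste, panel, grid_step = 0.1, tau_w = 4.5) {
  m <- exprsMatrix(ste)
  missing <- setdiff(panel, rownames(m))
  if (length(missing))
    stop("panel gene(s) missing from the dataset: ",
         paste(missing, collapse = ", "))
  sheet <- sampleSheet(ste)
  tp <- sort(unique(sheet$time_h))
  x <- m[panel, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  if (any(sdv <= 0))
    stop("panel gene(s) with zero variance in training data: ",
         paste(panel[sdv <= 0], collapse = ", "))
  z <- (x - mu) / sdv
  centroids <- vapply(tp, function(t)
    rowMeans(z[, sheet$time_h == t, drop = FALSE]),
    numeric(length(panel)))
  dimnames(centroids) <- list(panel, tp)
  new("ClockModel", panel = panel,
      gene_mean = setNames(mu, panel), gene_sd = setNames(sdv, panel),
      centroids = centroids, timepoints_h = tp,
      grid_step = grid_step, tau_w = tau_w)
}

#' Estimate hours since stroke onset for one blood sample
#'
#' Standardizes the sample's panel values with the training statistics
#' and finds the time on a dense grid whose interpolated centroid curve
#' (piecewise linear in log(1 + t)) is closest in mean squared deviation.
#' Ties break toward the earliest time (clinically conservative).
#'
#' @param model a \linkS4class{ClockModel}.
#' @param sample_vector named numeric vector of raw log2 values; at least
#'   2 panel genes must be present (missing genes are dropped with a
#'   warning).
#' @return list with \code{t_hat} (hours), \code{score} (mean squared
#'   deviation at the estimate) and \code{window} ("within" when
#'   \code{t_hat <= tau_w}, else "beyond").
#' @export
estimateTime <- function(model, sample_vector) {
  have <- intersect(model@panel, names(sample_vector))
  if (length(have) < length(model@panel))
    warning("dropping ", length(model@panel) - length(have),
            " panel gene(s) absent from the sample")
  if (length(have) < 2)
    stop("need values for at least 2 panel genes")
  z <- (sample_vector[have] - model@gene_mean[have]) / model@gene_sd[have]
  grid <- sort(unique(c(seq(0, 24, by = model@grid_step),
                        model@timepoints_h)))
  u_tp <- log1p(model@timepoints_h)
  u_grid <- log1p(grid)
  curves <- vapply(have, function(g)
    approx(u_tp, model@centroids[g, ], xout = u_grid)$y,
    numeric(length(grid)))
  scores <- rowMeans((curves - matrix(z, nrow = length(grid),
                                      ncol = length(have),
                                      byrow = TRUE))^2)
  i <- which.min(scores)   # first minimum = earliest time on ties
  list(t_hat = grid[i], score = scores[i],
       window = if (grid[i] <= model@tau_w) "within" else "beyond")
}

#' Leave-one-animal-out evaluation of the stroke clock
#'
#' For each animal, trains the clock on the remaining animals and
#' estimates the time of every held-out sample; reports per-sample
#' estimates, the median absolute error in hours and the accuracy of the
#' binary therapeutic-window call (true time vs estimate, threshold
#' \code{tau_w}).
#'
#' @param ste a \linkS4class{StrokeTimecourseExperiment} with >= 2
#'   animals.
#' @param panel panel gene IDs.
#' @param grid_step,tau_w passed to \code{\link{trainClock}}.
#' @return list with \code{estimates} (data.frame: sample_id, animal,
#'   time_h, t_hat, abs_error, window_true, window_est),
#'   \code{median_abs_error} and \code{window_accuracy}.
#' @export
evaluateLOAO <- function(ste, panel, grid_step = 0.1, tau_w = 4.5) {
  sheet <- sampleSheet(ste)
  animals <- unique(sheet$animal)
  if (length(animals) < 2) stop("need at least 2 animals for LOAO")
  m <- exprsMatrix(ste)
  rows <- lapply(animals, function(a) {
    tr <- sheet$sample_id[sheet$animal != a]
    te <- sheet$sample_id[sheet$animal == a]
    sub <- StrokeTimecourseExperiment(
      m[, tr, drop = FALSE], sheet[sheet$animal != a, , drop = FALSE])
    model <- trainClock(sub, panel, grid_step = grid_step, tau_w = tau_w)
    do.call(rbind, lapply(te, function(s) {
      est <- estimateTime(model, m[, s])
      t_true <- sheet$time_h[sheet$sample_id == s]
      data.frame(sample_id = s, animal = a, time_h = t_true,
                 t_hat = est$t_hat,
                 abs_error = abs(est$t_hat - t_true),
                 window_true = if (t_true <= tau_w) "within" else "beyond",
                 window_est = est$window,
                 stringsAsFactors = FALSE)
    }))
  })
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  list(estimates = est,
       median_abs_error = median(est$abs_error),
       window_accuracy = mean(est$window_true == est$window_est))
}

#' Serialize a clock model to JSON
#'
#' @param model a \linkS4class{ClockModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClockModel <- function(model, path) {
  obj <- list(panel = model@panel,
              gene_mean = as.list(model@gene_mean),
              gene_sd = as.list(model@gene_sd),
              centroids = apply(model@centroids, 1, as.list,
                                simplify = FALSE),
              timepoints_h = model@timepoints_h,
              grid_step = model@grid_step, tau_w = model@tau_w)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a clock model from JSON
#'
#' @param path JSON file written by \code{\link{writeClockModel}}.
#' @return A \linkS4class{ClockModel}.
#' @export
readClockModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- do.call(rbind, lapply(obj$panel, function(g)
    unlist(obj$centroids[[g]])))
  dimnames(centroids) <- list(obj$panel, obj$timepoints_h)
  new("ClockModel", panel = obj$panel,
      gene_mean = unlist(obj$gene_mean)[obj$panel],
      gene_sd = unlist(obj$gene_sd)[obj$panel],
      centroids = centroids, timepoints_h = obj$timepoints_h,
      grid_step = obj$grid_step, tau_w = obj$tau_w)
}
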