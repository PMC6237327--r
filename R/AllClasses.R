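#' @import methods
#' @importFrom stats approx cor kmeans ks.test median p.adjust pf quantile
#'   rnorm runif sd setNames var
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

#' StudyDesign: the sampling layout of a stroke time-course experiment
#'
#' Describes how blood samples are laid out over animals and hours after
#' vessel occlusion: how many animals, which sampling times, which
#' (animal, time) cells are missing, and an optional batch assignment.
#' The default corresponds to 8 animals sampled at 0, 1, 2, 3, 6 and 24 h
#' with the 6 h sample of animal 3 absent, giving 47 samples in total.
#'
#' @slot n_animals integer, number of animals.
#' @slot timepoints_h numeric, strictly increasing sampling times in hours.
#' @slot missing data.frame with columns \code{animal}, \code{time_h}
#'   listing absent samples.
#' @slot batches character, one batch label per (non-missing) sample, or
#'   length zero when batches are not modeled.
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(
    n_animals    = "integer",
    timepoints_h = "numeric",
    missing      = "data.frame",
    batches      = "character"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@n_animals < 1L)
    msg <- c(msg, "n_animals must be >= 1")
  tp <- object@timepoints_h
  if (length(tp) < 1L || any(diff(tp) <= 0))
    msg <- c(msg, "timepoints_h must be strictly increasing")
  m <- object@missing
  if (nrow(m)) {
    if (!all(c("animal", "time_h") %in% names(m)))
      msg <- c(msg, "missing must have columns 'animal' and 'time_h'")
    else {
      if (!all(m$animal %in% seq_len(object@n_animals)))
        msg <- c(msg, "missing refers to an animal outside 1..n_animals")
      if (!all(m$time_h %in% tp))
        msg <- c(msg, "missing refers to a time not in timepoints_h")
      if (anyDuplicated(m))
        msg <- c(msg, "duplicated rows in missing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' @param n_animals number of animals (default 8).
#' @param timepoints_h sampling times in hours, strictly increasing
#'   (default \code{c(0, 1, 2, 3, 6, 24)}).
#' @param missing data.frame of absent (animal, time_h) cells; the default
#'   drops the 6 h sample of animal 3.
#' @param batches optional character vector of batch labels, one per sample
#'   in sample-sheet order; empty to disable batch effects.
#' @return A \linkS4class{StudyDesign} object.
#' @examples
#' d <- studyDesign()
#' nSamples(d)  # 47
#' @export
studyDesign <- function(n_animals = 8L,
                        timepoints_h = c(0, 1, 2, 3, 6, 24),
                        missing = data.frame(animal = 3L, time_h = 6),
                        batches = character()) {
  new("StudyDesign",
      n_animals = as.integer(n_animals),
      timepoints_h = as.numeric(timepoints_h),
      missing = as.data.frame(missing),
      batches = as.character(batches))
}

#' @describeIn studyDesign number of collected samples under the design
#' @param design a \linkS4class{StudyDesign}.
#' @export
nSamples <- function(design) {
  design@n_animals * length(design@timepoints_h) - nrow(design@missing)
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@n_animals, "animals x",
      length(object@timepoints_h), "timepoints (",
      paste(object@timepoints_h, collapse = ", "), "h );",
      nrow(object@missing), "missing sample(s);",
      nSamples(object), "samples total\n")
})

#' StrokeTimecourseExperiment: expression container for the time course
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a genes x
#' samples log2 expression matrix (assay \code{"exprs"}) together with the
#' sample sheet in \code{colData} (columns \code{animal}, \code{time_h},
#' \code{batch}). Synthetic datasets additionally carry per-gene ground
#' truth (\code{archetype}, \code{amplitude}, \code{baseline}) in
#' \code{rowData} and the generator settings in \code{metadata}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass StrokeTimecourseExperiment
setClass("StrokeTimecourseExperiment", contains = "SummarizedExperiment")

setValidity("StrokeTimecourseExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("animal", "time_h")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData must contain 'animal' and 'time_h'")
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  if (length(msg)) msg else TRUE
})

#' Build a StrokeTimecourseExperiment from a matrix and sample sheet
#'
#' @param exprs genes x samples numeric matrix (log2 scale), with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param sample_sheet data.frame with columns \code{sample_id},
#'   \code{animal}, \code{time_h} and optionally \code{batch}; rows are
#'   matched to matrix columns by \code{sample_id}.
#' @param truth optional per-gene truth data.frame (columns
#'   \code{archetype}, \code{amplitude}, \code{baseline}).
#' @param metadata optional list of generator/run settings.
#' @return A \linkS4class{StrokeTimecourseExperiment}.
#' @export
StrokeTimecourseExperiment <- function(exprs, sample_sheet, truth = NULL,
                                       metadata = list()) {
  stopifnot(is.matrix(exprs), !is.null(colnames(exprs)))
  if (!all(c("sample_id", "animal", "time_h") %in% names(sample_sheet)))
    stop("sample_sheet needs columns sample_id, animal, time_h")
  idx <- match(colnames(exprs), sample_sheet$sample_id)
  if (anyNA(idx))
    stop("matrix columns missing from sample sheet: ",
         paste(colnames(exprs)[is.na(idx)], collapse = ", "))
  cd <- sample_sheet[idx, setdiff(names(sample_sheet), "sample_id"),
                     drop = FALSE]
  rownames(cd) <- sample_sheet$sample_id[idx]
  if (is.null(cd$batch)) cd$batch <- "b1"
  rd <- if (is.null(truth)) NULL else S4Vectors::DataFrame(truth)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(cd),
    rowData = rd,
    metadata = metadata)
  new("StrokeTimecourseExperiment", se)
}

#' @describeIn StrokeTimecourseExperiment the log2 expression matrix
#' @param x a \linkS4class{StrokeTimecourseExperiment}.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn StrokeTimecourseExperiment the sample sheet as a data.frame
#'   (sample_id, animal, time_h, batch)
#' @export
sampleSheet <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @describeIn StrokeTimecourseExperiment sampling times (hours) per sample
#' @export
timeHours <- function(x) SummarizedExperiment::colData(x)$time_h

setMethod("show", "StrokeTimecourseExperiment", function(object) {
  cat("StrokeTimecourseExperiment:", nrow(object), "genes x",
      ncol(object), "samples\n")
  tt <- table(timeHours(object))
  cat("  samples per timepoint:",
      paste(sprintf("%sh:%d", names(tt), tt), collapse = " "), "\n")
  rd <- SummarizedExperiment::rowData(object)
  if ("archetype" %in% names(rd)) {
    sig <- sum(rd$archetype != "NULL")
    cat("  ground truth: ", sig, " signal genes, ",
        nrow(object) - sig, " null genes\n", sep = "")
  }
})

#' ModeratedResult: moderated F-test results for every gene
#'
#' Per-gene output of the empirical-Bayes moderated F-test together with
#' the moderation hyperparameters.
#'
#' @slot table data.frame with columns \code{gene_id}, \code{F}, \code{p},
#'   \code{p_adj} (Benjamini-Hochberg, informational), \code{rank},
#'   \code{significant}, \code{df_residual}, \code{zero_df} (flag for genes
#'   with no residual degrees of freedom, reported with p = 1).
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s02 prior variance.
#' @slot df_numerator numerator degrees of freedom of the F-test.
#' @slot alpha significance cutoff used for the \code{significant} flag.
#' @exportClass ModeratedResult
setClass("ModeratedResult",
  representation(table = "data.frame", d0 = "numeric", s02 = "numeric",
                 df_numerator = "numeric", alpha = "numeric"))

setMethod("show", "ModeratedResult", function(object) {
  cat("ModeratedResult:", nrow(object@table), "genes; moderated F with",
      object@df_numerator, "numerator df\n")
  cat(sprintf("  prior: d0 = %s, s0^2 = %.4g\n",
              format(object@d0), object@s02))
  cat(sprintf("  %d genes significant at alpha = %g\n",
              sum(object@table$significant), object@alpha))
})

#' @describeIn ModeratedResult ranked result table (sorted by ascending p)
#' @param object a \linkS4class{ModeratedResult}.
#' @export
resultTable <- function(object) object@table

#' ClusterResult: K-means partition of standardized temporal profiles
#'
#' @slot K number of clusters.
#' @slot cluster named integer vector, cluster index per gene (NA for
#'   degenerate all-tied profiles that were excluded).
#' @slot centers K x timepoints matrix of centroids in rank z-score space.
#' @slot inertia total within-cluster sum of squares of the selected run.
#' @slot seed random seed used.
#' @slot n_init number of random restarts.
#' @slot archetype character vector, archetype label per cluster centroid.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(K = "integer", cluster = "integer", centers = "matrix",
                 inertia = "numeric", seed = "integer", n_init = "integer",
                 archetype = "character"))

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: K =", object@K, "clusters over",
      sum(!is.na(object@cluster)), "profiles (inertia",
      format(object@inertia, digits = 6), ")\n")
  if (length(object@archetype)) {
    sizes <- tabulate(object@cluster, nbins = object@K)
    cat("  centroid archetypes:",
        paste(sprintf("%d:%s(%d)", seq_len(object@K), object@archetype,
                      sizes), collapse = " "), "\n")
  }
})

#' @describeIn ClusterResult cluster assignment per gene
#' @param object a \linkS4class{ClusterResult}.
#' @export
clusterAssignments <- function(object) object@cluster

#' @describeIn ClusterResult archetype label of each cluster centroid
#' @export
centroidArchetypes <- function(object) object@archetype

#' ClockModel: trained stroke-clock panel
#'
#' A nearest-profile estimator of hours since stroke onset. For each panel
#' gene the model stores the training mean and SD (used to standardize a
#' new sample) and the standardized per-timepoint centroid curve;
#' estimation matches a standardized sample against the centroid curves
#' interpolated on a dense grid in log(1 + t).
#'
#' @slot panel character, panel gene IDs.
#' @slot gene_mean,gene_sd named numeric, per-gene training statistics.
#' @slot centroids genes x timepoints matrix of standardized training
#'   means.
#' @slot timepoints_h numeric, design timepoints (hours).
#' @slot grid_step numeric, grid resolution in hours.
#' @slot tau_w numeric, therapeutic-window threshold in hours
#'   (default 4.5).
#' @exportClass ClockModel
setClass("ClockModel",
  representation(panel = "character", gene_mean = "numeric",
                 gene_sd = "numeric", centroids = "matrix",
                 timepoints_h = "numeric", grid_step = "numeric",
                 tau_w = "numeric"))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!length(object@panel)) msg <- c(msg, "panel must be non-empty")
  if (any(!is.finite(object@gene_sd)) || any(object@gene_sd <= 0))
    msg <- c(msg, "every panel gene needs finite SD > 0")
  if (object@tau_w <= 0 || object@tau_w >= 24)
    msg <- c(msg, "tau_w must lie in (0, 24)")
  if (min(object@timepoints_h) > 0 || max(object@timepoints_h) < 24)
    msg <- c(msg, "timepoints must cover [0, 24]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel:", length(object@panel), "panel genes;",
      "grid step", object@grid_step, "h; window threshold",
      object@tau_w, "h\n")
  cat("  panel:", paste(utils::head(object@panel, 8), collapse = ", "),
      if (length(object@panel) > 8) "..." else "", "\n")
})

#' @describeIn ClockModel panel gene identifiers
#' @param object a \linkS4class{ClockModel}.
#' @export
clockPanel <- function(object) object@panel
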