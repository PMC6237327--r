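#' Build the sample sheet implied by a StudyDesign
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return data.frame with columns \code{sample_id}, \code{animal},
#'   \code{time_h}, \code{batch}, one row per collected sample, ordered by
#'   timepoint then animal.
#' @export
designSampleSheet <- function(design = studyDesign()) {
  grid <- expand.grid(animal = seq_len(design@n_animals),
                      time_h = design@timepoints_h,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(design@missing)) {
    drop <- paste(design@missing$animal, design@missing$time_h)
    grid <- grid[!(paste(grid$animal, grid$time_h) %in% drop), ,
                 drop = FALSE]
  }
  grid <- grid[order(grid$time_h, grid$animal), , drop = FALSE]
  batch <- if (length(design@batches)) {
    if (length(design@batches) != nrow(grid))
      stop("batches must have one label per sample (", nrow(grid), ")")
    design@batches
  } else rep("b1", nrow(grid))
  data.frame(
    sample_id = sprintf("a%d_t%g", grid$animal, grid$time_h),
    animal = grid$animal, time_h = grid$time_h, batch = batch,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a stroke blood-transcriptome time course with known truth
#'
#' Generates a log2 expression matrix under the study design: each signal
#' gene follows one of the eight temporal archetypes with expectation
#' baseline + amplitude x shape(time) (+ optional batch offset), null
#' genes stay at baseline, and i.i.d. Gaussian noise is added everywhere.
#' Gene-level ground truth (archetype, amplitude, baseline) is stored in
#' \code{rowData} so recovery experiments can score themselves.
#'
#' @param design a \linkS4class{StudyDesign}; default is the 8-animal,
#'   six-timepoint, 47-sample layout.
#' @param archetype_counts named integer vector, number of genes per
#'   archetype label A-H (labels may be omitted). The study's cluster
#'   composition is \code{c(A=58, B=231, C=37, D=120, E=71, F=6, G=83,
#'   H=40)}.
#' @param n_null number of unresponsive (baseline-only) genes.
#' @param amplitude amplitude in log2 units for signal genes: a single
#'   number or a function \code{function(n)} drawing n amplitudes.
#'   Default 1.5.
#' @param noise_sd Gaussian noise SD in log2 units (default 0.25).
#' @param baseline_range range of the uniform baseline draw, log2 units.
#' @param batch_offsets optional named numeric of per-batch additive
#'   offsets (log2 units); default none.
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @return A \linkS4class{StrokeTimecourseExperiment}.
#' @examples
#' ste <- simulateTimecourse(archetype_counts = c(A = 5), n_null = 10,
#'                           seed = 1)
#' dim(ste)  # 15 x 47
#' @export
simulateTimecourse <- function(design = studyDesign(),
                               archetype_counts = integer(),
                               n_null = 0L,
                               amplitude = 1.5,
                               noise_sd = 0.25,
                               baseline_range = c(4, 12),
                               batch_offsets = NULL,
                               seed) {
  if (missing(seed)) stop("a seed must be provided")
  counts <- archetype_counts
  if (length(counts)) {
    if (is.null(names(counts)) ||
        !all(names(counts) %in% names(archetypeShapes)))
      stop("archetype_counts must be named with labels A..H")
    if (any(counts < 0)) stop("archetype counts must be >= 0")
  }
  if (n_null < 0) stop("n_null must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  sheet <- designSampleSheet(design)
  labels <- c(rep(names(counts), times = counts),
              rep("NULL", n_null))
  n_genes <- length(labels)
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  set.seed(as.integer(seed))
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
  n_signal <- sum(labels != "NULL")
  amp <- numeric(n_genes)
  amp[labels != "NULL"] <- if (is.function(amplitude))
    amplitude(n_signal) else rep(amplitude, n_signal)
  if (any(amp < 0)) stop("amplitudes must be >= 0")

  shape_at <- matrix(0, n_genes, length(design@timepoints_h))
  for (g in seq_len(n_genes))
    shape_at[g, ] <- archetypeProfile(labels[g], design@timepoints_h)
  # expectation: rows genes, cols samples
  tp_idx <- match(sheet$time_h, design@timepoints_h)
  mu <- baseline + amp * shape_at[, tp_idx, drop = FALSE]
  if (!is.null(batch_offsets)) {
    off <- batch_offsets[sheet$batch]
    if (anyNA(off)) stop("batch_offsets missing a label used in the design")
    mu <- sweep(mu, 2, off, "+")
  }
  noise <- if (noise_sd > 0)
    matrix(rnorm(n_genes * nrow(sheet), sd = noise_sd),
           nrow = n_genes, ncol = nrow(sheet)) else 0
  m <- mu + noise
  dimnames(m) <- list(gene_id, sheet$sample_id)

  truth <- data.frame(gene_id = gene_id, archetype = labels,
                      amplitude = amp, baseline = baseline,
                      row.names = gene_id, stringsAsFactors = FALSE)
  StrokeTimecourseExperiment(
    m, sheet, truth = truth,
    metadata = list(noise_sd = noise_sd, seed = as.integer(seed),
                    design = design))
}

#' Ground-truth table of a synthetic dataset
#'
#' @param ste a \linkS4class{StrokeTimecourseExperiment} produced by
#'   \code{\link{simulateTimecourse}}.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{archetype}, \code{amplitude}, \code{baseline}.
#' @export
truthTable <- function(ste) {
  rd <- SummarizedExperiment::rowData(ste)
  if (!all(c("archetype", "amplitude", "baseline") %in% names(rd)))
    stop("no ground truth stored in this dataset")
  df <- as.data.frame(rd)
  rownames(df) <- NULL
  df
}
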