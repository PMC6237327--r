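#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Duplicate gene IDs are rejected; blank cells become NA; any other
#' non-numeric cell raises an error naming its row and column.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  gene_id <- df[[1]]
  if (anyDuplicated(gene_id))
    stop("duplicate gene ID(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(gene_id, names(vals)))
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop("non-numeric value '", v[bad[1]], "' at gene ",
           gene_id[bad[1]], ", sample ", names(vals)[j])
    m[, j] <- num
  }
  m
}

#' Write an expression matrix as TSV
#'
#' First column \code{gene_id}, then one column per sample; full
#' precision so that write/read round-trips exactly.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExpression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' @param path CSV with columns \code{sample_id}, \code{animal},
#'   \code{time_h} and optionally \code{batch}.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal", "time_h")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$batch)) df$batch <- "b1"
  df
}

#' Write a sample sheet as CSV
#'
#' @param sheet data.frame with \code{sample_id}, \code{animal},
#'   \code{time_h}, \code{batch}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a sample manifest against a study design
#'
#' Computes totals and per-timepoint / per-animal sample counts, rejects
#' duplicated (animal, time) cells, and reports mismatches against the
#' declared design as warnings.
#'
#' @param sample_sheet data.frame with \code{animal} and \code{time_h}.
#' @param design a \linkS4class{StudyDesign} to check against (optional).
#' @return list with \code{total}, \code{per_timepoint},
#'   \code{per_animal} and \code{design_mismatches} (character vector).
#' @examples
#' validateManifest(designSampleSheet(studyDesign()))$total  # 47
#' @export
validateManifest <- function(sample_sheet, design = NULL) {
  key <- paste(sample_sheet$animal, sample_sheet$time_h)
  if (anyDuplicated(key))
    stop("duplicate (animal, time) sample(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  tp <- sort(unique(sample_sheet$time_h))
  per_tp <- vapply(tp, function(t) sum(sample_sheet$time_h == t),
                   integer(1))
  names(per_tp) <- paste0("t", tp)
  an <- sort(unique(sample_sheet$animal))
  per_an <- vapply(an, function(a) sum(sample_sheet$animal == a),
                   integer(1))
  names(per_an) <- paste0("animal", an)
  mism <- character()
  if (!is.null(design)) {
    if (!all(tp %in% design@timepoints_h))
      mism <- c(mism, paste("unexpected timepoint(s):",
                            paste(setdiff(tp, design@timepoints_h),
                                  collapse = ", ")))
    bad_an <- setdiff(an, seq_len(design@n_animals))
    if (length(bad_an))
      mism <- c(mism, paste("unexpected animal(s):",
                            paste(bad_an, collapse = ", ")))
    if (nrow(sample_sheet) != nSamples(design))
      mism <- c(mism, sprintf("expected %d samples, found %d",
                              nSamples(design), nrow(sample_sheet)))
    if (length(mism))
      warning("manifest does not match the declared design: ",
              paste(mism, collapse = "; "))
  }
  list(total = nrow(sample_sheet), per_timepoint = per_tp,
       per_animal = per_an, design_mismatches = mism)
}

#' Check reported volume arithmetic
#'
#' Flags whether the sum of reported part means (e.g. striatal and
#' cortical infarct volumes) equals the reported total mean within a
#' rounding tolerance.
#'
#' @param total_mean reported total mean.
#' @param part_means numeric vector of reported part means.
#' @param tol rounding tolerance (default 0.01).
#' @return list with \code{consistent} (logical) and \code{residual}
#'   (total minus sum of parts).
#' @examples
#' checkVolumeArithmetic(205.76, c(36.76, 169.0))$consistent  # TRUE
#' @export
checkVolumeArithmetic <- function(total_mean, part_means, tol = 0.01) {
  residual <- total_mean - sum(part_means)
  list(consistent = abs(residual) <= tol, residual = residual)
}

#' Write a generic result table as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
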