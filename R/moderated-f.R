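#' Cell-means design matrix over the time factor
#'
#' One indicator column per timepoint level, so the fitted coefficients
#' are the per-timepoint means and neighboring-timepoint contrasts are
#' direct differences of coefficients.
#'
#' @param sample_sheet data.frame with a \code{time_h} column.
#' @param levels the admissible time levels, in order; defaults to the
#'   sorted unique times of the sheet.
#' @return samples x levels 0/1 matrix with attribute \code{"levels"};
#'   levels with no samples are reported in attribute \code{"empty"}.
#' @examples
#' X <- buildDesign(designSampleSheet(studyDesign()))
#' colSums(X)  # 8 8 8 8 7 8
#' @export
buildDesign <- function(sample_sheet, levels = NULL) {
  t_h <- sample_sheet$time_h
  if (is.null(levels)) levels <- sort(unique(t_h))
  if (!all(t_h %in% levels))
    stop("sample(s) at time(s) not in the design levels: ",
         paste(unique(t_h[!t_h %in% levels]), collapse = ", "))
  X <- outer(t_h, levels, "==") * 1
  dimnames(X) <- list(sample_sheet$sample_id, paste0("t", levels))
  attr(X, "levels") <- levels
  attr(X, "empty") <- levels[colSums(X) == 0]
  X
}

#' Contrast matrix of neighboring-timepoint differences
#'
#' Successive differences between adjacent time levels (1-0, 2-1, 3-2,
#' 6-3, 24-6 under the default design). The rows jointly span the full
#' between-time space, so an F-test over them is the one-way ANOVA F.
#'
#' @param levels ordered time levels (>= 2).
#' @return (length(levels) - 1) x length(levels) matrix; each row sums to
#'   zero with one +1 (later time) and one -1 (earlier time).
#' @export
neighboringContrasts <- function(levels) {
  k <- length(levels)
  if (k < 2) stop("need at least 2 time levels for contrasts")
  C <- matrix(0, k - 1, k,
              dimnames = list(
                paste0("t", levels[-1], "-t", levels[-k]),
                paste0("t", levels)))
  for (i in seq_len(k - 1)) {
    C[i, i] <- -1
    C[i, i + 1] <- 1
  }
  C
}

#' Per-gene ordinary least squares on the time-factor design
#'
#' Under cell-means coding the coefficient vector is the per-timepoint
#' arithmetic mean of each gene; the residual variance is RSS divided by
#' the residual degrees of freedom (samples used minus estimable levels).
#' Missing cells (NA) are dropped per gene without imputation.
#'
#' @param exprs genes x samples matrix, or a
#'   \linkS4class{StrokeTimecourseExperiment}.
#' @param design design matrix from \code{\link{buildDesign}} (built from
#'   the dataset's sample sheet when \code{exprs} is an experiment
#'   object).
#' @return A list with elements \code{coefficients} (genes x levels),
#'   \code{sigma2}, \code{df} (residual df per gene), \code{counts}
#'   (genes x levels samples used), \code{levels} and \code{zero_df}
#'   (flag for genes with no residual degrees of freedom).
#' @export
fitGeneModels <- function(exprs, design = NULL) {
  if (is(exprs, "StrokeTimecourseExperiment")) {
    if (is.null(design)) design <- buildDesign(sampleSheet(exprs))
    exprs <- exprsMatrix(exprs)
  }
  if (is.null(design)) stop("a design matrix is required")
  if (ncol(exprs) != nrow(design))
    stop("design rows must match matrix columns")
  if (any(rowSums(!is.na(exprs)) == 0))
    stop("gene(s) with all samples missing: ",
         paste(rownames(exprs)[rowSums(!is.na(exprs)) == 0],
               collapse = ", "))
  levels <- attr(design, "levels")
  obs <- !is.na(exprs)
  counts <- obs %*% design                       # genes x levels
  sums <- exprs
  sums[!obs] <- 0
  sums <- sums %*% design
  beta <- sums / counts                          # per-level means (NaN if empty)
  # RSS = sum x^2 - sum_t n_t beta_t^2, per gene
  ss_tot <- rowSums(exprs^2, na.rm = TRUE)
  b2 <- beta
  b2[counts == 0] <- 0
  ss_model <- rowSums(counts * b2^2)
  rss <- pmax(ss_tot - ss_model, 0)
  df <- rowSums(counts) - rowSums(counts > 0)
  sigma2 <- ifelse(df > 0, rss / df, NA_real_)
  list(coefficients = beta, sigma2 = sigma2, df = df, counts = counts,
       levels = levels, zero_df = df == 0)
}

.trigammaInverse <- function(y) {
  # monotone bisection of trigamma on (lo, hi); trigamma is decreasing
  vapply(y, function(v) {
    if (!is.finite(v) || v <= trigamma(1e6)) return(1e6)
    lo <- 1e-8
    hi <- 1e6
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > v) lo <- mid else hi <- mid
      if (hi - lo < 1e-12 * max(1, hi)) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Empirical-Bayes prior for gene-wise variances
#'
#' Estimates the hyperparameters (d0, s0^2) of a scaled inverse-chi-square
#' prior on the true gene variances by moment-matching on the log scale:
#' with e_g = log s2_g - digamma(d_g/2) + log(d_g/2), the excess of the
#' empirical variance of e_g over the mean sampling variance
#' trigamma(d_g/2) equals trigamma(d0/2), inverted by monotone bisection;
#' the mean of e_g then yields s0^2. When the empirical spread does not
#' exceed the sampling variance the prior is degenerate: d0 = Inf and
#' s0^2 is the pooled residual variance.
#'
#' @param fits output of \code{\link{fitGeneModels}}. Genes without
#'   residual degrees of freedom are excluded.
#' @return list with elements \code{d0} and \code{s02}.
#' @export
estimateVariancePrior <- function(fits) {
  keep <- fits$df > 0 & is.finite(fits$sigma2) & fits$sigma2 > 0
  if (sum(keep) < 2)
    stop("need at least 2 genes with positive residual df")
  s2 <- fits$sigma2[keep]
  d <- fits$df[keep]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e)
  excess <- evar - mean(trigamma(d / 2))
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf,
                s02 = sum(d * s2) / sum(d)))
  }
  d0 <- 2 * .trigammaInverse(excess)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated F-test over a contrast set
#'
#' Shrinks each gene's residual variance toward the prior,
#' s2_tilde = (d0 s0^2 + d s2) / (d0 + d), and tests the contrast set C
#' with F = (C b)' [C (X'X)^-1 C']^-1 (C b) / (r s2_tilde) on
#' (r, d0 + d) degrees of freedom. With d0 = 0 this is the classical
#' F-test; with d0 = Inf the denominator is s0^2 for every gene. When the
#' contrasts span the full between-time space (the default
#' neighboring-timepoint set does) the numerator equals the between-group
#' sum of squares of the one-way layout, which is how it is computed.
#'
#' @param fits output of \code{\link{fitGeneModels}}.
#' @param contrasts contrast matrix from
#'   \code{\link{neighboringContrasts}}.
#' @param prior list with \code{d0}, \code{s02} from
#'   \code{\link{estimateVariancePrior}} (or set manually, e.g.
#'   \code{list(d0 = 0)} for the unmoderated test).
#' @param alpha significance cutoff applied downstream (stored in the
#'   result; default 5e-7).
#' @return A \linkS4class{ModeratedResult}; its table is sorted by
#'   ascending p (ties broken by gene ID).
#' @export
moderatedFTest <- function(fits, contrasts = neighboringContrasts(fits$levels),
                           prior, alpha = 5e-7) {
  r <- nrow(contrasts)
  d0 <- prior$d0
  s02 <- if (d0 > 0) prior$s02 else 0
  beta <- fits$coefficients
  counts <- fits$counts
  G <- nrow(beta)
  full_span <- r == (ncol(beta) - 1)
  if (full_span) {
    # between-group SS of the one-way layout
    b <- beta
    b[counts == 0] <- 0
    gm <- rowSums(counts * b) / rowSums(counts)
    ss_c <- rowSums(counts * (b - gm)^2)
  } else {
    ss_c <- vapply(seq_len(G), function(g) {
      ok <- counts[g, ] > 0
      Cg <- contrasts[, ok, drop = FALSE]
      if (any(rowSums(abs(contrasts[, !ok, drop = FALSE])) > 0))
        stop("contrast involves an empty time level")
      V <- Cg %*% diag(1 / counts[g, ok], sum(ok)) %*% t(Cg)
      cb <- Cg %*% beta[g, ok]
      qf <- try(solve(V, cb), silent = TRUE)
      if (inherits(qf, "try-error"))
        stop("singular contrast covariance for gene ", rownames(beta)[g])
      drop(crossprod(cb, qf))
    }, numeric(1))
  }
  d <- fits$df
  s2 <- ifelse(is.na(fits$sigma2), 0, fits$sigma2)
  s2_tilde <- if (is.infinite(d0)) rep(s02, G)
              else (d0 * s02 + d * s2) / (d0 + d)
  Fg <- ss_c / (r * s2_tilde)
  df2 <- d0 + d
  p <- pf(Fg, r, df2, lower.tail = FALSE)
  # genes without residual df are reported, flagged, with p = 1
  if (any(fits$zero_df)) {
    p[fits$zero_df] <- 1
    Fg[fits$zero_df] <- NA_real_
  }
  gene_id <- rownames(beta)
  tab <- data.frame(gene_id = gene_id, F = Fg, p = p,
                    df_residual = d, zero_df = fits$zero_df,
                    stringsAsFactors = FALSE)
  ord <- order(tab$p, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab$rank <- seq_len(nrow(tab))
  tab$significant <- tab$p < alpha
  rownames(tab) <- NULL
  new("ModeratedResult", table = tab,
      d0 = d0, s02 = if (d0 > 0) s02 else NA_real_,
      df_numerator = r, alpha = alpha)
}

#' Rank genes by significance and apply a fixed cutoff
#'
#' @param result a \linkS4class{ModeratedResult}, or a data.frame with at
#'   least \code{gene_id} and \code{p}.
#' @param alpha significance cutoff in (0, 1); the study used 5e-7 after
#'   an initial 0.05.
#' @return data.frame sorted by ascending p (ties broken by gene ID) with
#'   columns \code{rank} and \code{significant} refreshed at this alpha.
#' @examples
#' rankAndThreshold(data.frame(gene_id = c("a", "b", "c"),
#'                             p = c(1e-9, 0.2, 3e-8)), alpha = 5e-7)
#' @export
rankAndThreshold <- function(result, alpha = 5e-7) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  tab <- if (is(result, "ModeratedResult")) resultTable(result) else result
  stopifnot(all(c("gene_id", "p") %in% names(tab)))
  tab <- tab[order(tab$p, tab$gene_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$significant <- tab$p < alpha
  rownames(tab) <- NULL
  tab
}
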