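#' Canonical temporal archetypes of the hyperacute stroke blood response
#'
#' Eight named temporal shapes (A-H) summarize the stereotyped blood
#' gene-expression patterns seen over the first 24 h after middle cerebral
#' artery occlusion: e.g. A is a hyperacute transient upregulation peaking
#' at 2 h and returning to baseline by 24 h, F a slow monotone
#' downregulation through 24 h, H an early downregulation at 1 h followed
#' by upregulation peaking at 3-6 h. Shapes are unit-amplitude relative
#' deviations from the 0 h baseline at the design timepoints
#' (0, 1, 2, 3, 6, 24 h); transient shapes return to within 20% of
#' baseline by 24 h.
#'
#' @format A named list of numeric vectors of length 6.
#' @export
archetypeShapes <- list(
  A = c(0,  0.5,  1.0,  0.5,  0.2,  0.0),
  B = c(0,  0.3,  0.6,  0.8,  1.0,  0.1),
  C = c(0, -0.1,  0.3,  0.6,  1.0, -0.2),
  D = c(0,  0.5,  1.0,  0.4,  0.9,  0.1),
  E = c(0, -0.3, -0.5, -0.7, -1.0, -0.4),
  F = c(0, -0.2, -0.4, -0.5, -0.7, -1.0),
  G = c(0, -0.5, -1.0, -0.95, -0.9, -0.3),
  H = c(0, -0.5,  0.2,  0.8,  1.0,  0.0)
)

.archetypeTimes <- c(0, 1, 2, 3, 6, 24)

#' Unit-amplitude temporal profile of a named archetype
#'
#' Returns the canonical unit shape of one of the eight archetypes (or the
#' all-zero null profile) evaluated at the design timepoints.
#'
#' @param label one of \code{"A"}..\code{"H"} or \code{"NULL"}.
#' @param timepoints_h sampling times in hours. Archetype shapes are
#'   defined on the canonical grid \code{c(0, 1, 2, 3, 6, 24)}; the null
#'   profile accepts any grid.
#' @return Numeric vector of relative deviations from baseline, named by
#'   timepoint.
#' @examples
#' archetypeProfile("A", c(0, 1, 2, 3, 6, 24))  # peaks at 2 h
#' @export
archetypeProfile <- function(label, timepoints_h = .archetypeTimes) {
  label <- as.character(label)
  if (identical(label, "NULL"))
    return(setNames(numeric(length(timepoints_h)), timepoints_h))
  if (!label %in% names(archetypeShapes))
    stop("unknown archetype label: '", label, "'")
  if (length(timepoints_h) != length(.archetypeTimes) ||
      !all(timepoints_h == .archetypeTimes))
    stop("archetype '", label, "' is defined on timepoints ",
         paste(.archetypeTimes, collapse = ", "), " h")
  setNames(archetypeShapes[[label]], timepoints_h)
}

#' Shape features of a 6-point temporal profile
#'
#' Computes the machine-checkable descriptors used to classify a
#' mean-centered averaged profile into an archetype: peak and trough times,
#' interior local maxima (strictly greater than both neighbors), the
#' direction and size of deviations relative to the 0 h value, an
#' endpoint-return flag (|x(24) - x(0)| <= 0.2 x range) and a plateau flag
#' over the 2-6 h window (spread <= 0.15 x range).
#'
#' @param profile numeric vector of length 6, a (mean-centered) profile at
#'   0, 1, 2, 3, 6, 24 h.
#' @param timepoints_h the timepoints the profile is evaluated at.
#' @return A list of features.
#' @export
shapeFeatures <- function(profile, timepoints_h = .archetypeTimes) {
  stopifnot(length(profile) == length(timepoints_h))
  x <- as.numeric(profile)
  rng <- max(x) - min(x)
  n <- length(x)
  interior <- which(vapply(seq(2, n - 1), function(i)
    x[i] > x[i - 1] && x[i] > x[i + 1], logical(1))) + 1L
  dev_up <- max(x - x[1])
  dev_down <- max(x[1] - x)
  win <- which(timepoints_h >= 2 & timepoints_h <= 6)
  list(
    peak_time = timepoints_h[which.max(x)],
    trough_time = timepoints_h[which.min(x)],
    n_interior_maxima = length(interior),
    interior_maxima_times = timepoints_h[interior],
    initial_step = x[2] - x[1],
    dev_up = dev_up,
    dev_down = dev_down,
    range = rng,
    non_increasing = all(diff(x) <= 0),
    endpoint_return = abs(x[n] - x[1]) <= 0.2 * rng,
    flat_at_1h = abs(x[2] - x[1]) <= 0.15 * rng,
    plateau_2_6 = (max(x[win]) - min(x[win])) <= 0.15 * rng,
    recovery_at_24 = x[n] > x[n - 1]
  )
}

#' Classify a temporal profile into an archetype
#'
#' Deterministic first-match rule cascade over \code{\link{shapeFeatures}},
#' formalizing the verbal archetype definitions: double-peaked upregulation
#' (D) is tested before the single-peak shapes A-C; monotone decline (F)
#' before the other downregulation shapes; plateau decline (G) before
#' progressive transient decline (E). Profiles matching no rule - including
#' flat profiles - are labeled \code{"OTHER"}.
#'
#' @param features output of \code{\link{shapeFeatures}} (or a profile
#'   vector, which is featurized first).
#' @param timepoints_h timepoints, used only when a raw profile is given.
#' @return A single archetype label in \code{A..H} or \code{"OTHER"}.
#' @examples
#' classifyArchetype(shapeFeatures(archetypeProfile("B")))  # "B"
#' @export
classifyArchetype <- function(features, timepoints_h = .archetypeTimes) {
  if (is.numeric(features))
    features <- shapeFeatures(features, timepoints_h)
  f <- features
  if (f$range <= .Machine$double.eps^0.5) return("OTHER")
  up <- f$dev_up >= f$dev_down
  if (f$n_interior_maxima >= 2 && up) return("D")
  if (f$non_increasing) return("F")
  if (up) {
    # 6 h-peak shapes differ by where the minimum sits: an early trough
    # is the biphasic H, a 24 h trough the delayed C, a 0 h trough B
    if (f$trough_time == 1 && f$peak_time %in% c(3, 6)) return("H")
    if (f$peak_time == 2 && f$endpoint_return) return("A")
    if (f$peak_time == 6) return(if (f$trough_time == 24) "C" else "B")
    return("OTHER")
  }
  # downregulation shapes differ by trough time: 24 h (handled above as
  # F), 6 h with recovery (E), or an early trough with plateau/recovery (G)
  if (f$trough_time == 6 && f$recovery_at_24) return("E")
  if (f$trough_time %in% c(2, 3)) return("G")
  "OTHER"
}
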