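#' Assembly quality score from pseudo-heterozygous calls
#'
#' Q = |-10 * log10(hetsites / totalsites)|: reads that could not map back
#' to their own (unassembled) gene pile onto related genes and appear as
#' pseudo-heterozygous sites, so a lower site ratio means a better
#' assembly. With zero hetsites the score is infinite (`Inf`, a perfect
#' assembly sentinel).
#'
#' @param hetsites pseudo-heterozygous site count (>= 0).
#' @param totalsites mappable NLR base count (> 0).
#' @return numeric quality score (vectorized).
#' @export
quality_score <- function(hetsites, totalsites) {
  if (any(totalsites <= 0)) stop("totalsites must be positive")
  if (any(hetsites < 0)) stop("hetsites must be non-negative")
  if (any(hetsites > totalsites)) stop("hetsites cannot exceed totalsites")
  ifelse(hetsites == 0, Inf, abs(-10 * log10(hetsites / totalsites)))
}

#' Assembly completeness ratio
#'
#' Fraction of the reference NLR complement covered by an assembly, in
#' bases.
#'
#' @param covered_bases covered NLR bases (>= 0).
#' @param total_reference_nlr_bases total reference NLR bases (> 0).
#' @return fraction in [0, 1] (vectorized).
#' @export
completeness_ratio <- function(covered_bases, total_reference_nlr_bases) {
  if (any(total_reference_nlr_bases <= 0))
    stop("total reference length must be positive")
  if (any(covered_bases < 0)) stop("covered bases must be non-negative")
  if (any(covered_bases > total_reference_nlr_bases))
    stop("covered bases cannot exceed the reference total")
  covered_bases / total_reference_nlr_bases
}

#' Completeness estimate from a quality calibration table
#'
#' Piecewise-linear interpolation of a monotone (quality, completeness)
#' calibration table (built from assemblies of down-sampled reference
#' reads); queries outside the calibrated range are clamped to the
#' nearest knot.
#'
#' @param q quality score(s) from [quality_score()].
#' @param calibration data.frame with columns `q` and `completeness`,
#'   completeness non-decreasing in q.
#' @return interpolated completeness estimate(s).
#' @export
completeness_from_quality <- function(q, calibration) {
  if (is.null(calibration) || nrow(calibration) < 2L)
    stop("calibration needs at least 2 points")
  ord <- order(calibration$q)
  cq <- calibration$q[ord]; cc <- calibration$completeness[ord]
  if (is.unsorted(cc)) stop("completeness must be non-decreasing in q")
  approx(cq, cc, xout = pmin(pmax(q, min(cq)), max(cq)),
         rule = 2, ties = "ordered")$y
}

#' Identity-by-state fraction of two genotype vectors
#'
#' Fraction of compared biallelic sites with identical calls; sites with a
#' missing call in either sample are excluded pairwise.
#'
#' @param genotypes_a,genotypes_b equal-length vectors of genotype calls
#'   (`NA` = missing).
#' @return fraction in [0, 1], or `NA` when no site is comparable.
#' @export
ibs <- function(genotypes_a, genotypes_b) {
  if (length(genotypes_a) != length(genotypes_b))
    stop("genotype vectors must have equal length")
  ok <- !(is.na(genotypes_a) | is.na(genotypes_b))
  if (!any(ok)) return(NA_real_)
  mean(genotypes_a[ok] == genotypes_b[ok])
}

#' Synthetic quality-completeness calibration table
#'
#' Generates a monotone calibration fixture emulating the shape obtained
#' from assemblies of progressively down-sampled reference reads: low
#' quality scores map to fragmented, incomplete assemblies and high
#' scores saturate near full completeness. Synthetic: a stand-in for a
#' calibration measured on real subsampled assemblies.
#'
#' @param n_knots number of calibration points (default 25).
#' @return data.frame with columns `q`, `completeness`.
#' @export
synthetic_calibration <- function(n_knots = 25L) {
  q <- seq(10, 58, length.out = n_knots)
  completeness <- 0.05 + 0.93 / (1 + exp(-(q - 30) / 6))
  data.frame(q = q, completeness = pmin(completeness, 0.99))
}
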