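#' Pipeline configuration
#'
#' Bundles every threshold and numerical constant used by interaction
#' scoring, hit selection, differential profiling and the permutation FDR,
#' so that a whole analysis is reproducible from a single object. The
#' defaults are the stringent criteria in common use for BioID screens:
#' a prey is a high-confidence hit when its average spectral count (SpC)
#' exceeds 10 in at least one bait condition, its interaction probability
#' exceeds 0.9 and its primary fold change FC-A exceeds 7, all within the
#' same condition; a hit is condition-preferred when its bait-normalized
#' ratio `R` exceeds 2 (or falls below 0.5) with a t-test p-value below
#' 0.05. All inequalities are strict.
#'
#' @param spc_min Minimum mean raw SpC for hit selection (strict `>`).
#' @param prob_min Minimum interaction probability (strict `>`).
#' @param fca_min Minimum FC-A fold change (strict `>`).
#' @param r_up Ratio threshold above which a hit is condition-A preferred.
#' @param r_down Ratio threshold below which a hit is condition-B
#'   preferred; defaults to `1 / r_up`.
#' @param alpha Two-sided t-test significance level for classification.
#' @param pseudocount Added to every normalized SpC before log2.
#' @param fca_floor Floor applied to the mean control SpC in the FC-A
#'   denominator so that preys absent from controls get a finite score.
#' @param prior Prior probability that a prey is a true interactor, used
#'   by the two-component Poisson probability model.
#' @param bg_floor Floor on the background (control) Poisson rate.
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   pooled-variance test.
#' @param use_normalized_spc Apply the mean-SpC hit criterion to
#'   bait-normalized rather than raw counts.
#' @param classify_all Classify every prey, not only selected hits.
#' @param adjust_p Benjamini-Hochberg adjust the per-prey p-values before
#'   classification (off by default: classification gates on raw p and a
#'   single global permutation FDR is reported instead).
#' @param max_permutations Cap on label reassignments; larger designs are
#'   Monte-Carlo sampled down to this many.
#' @param seed Integer seed for any Monte-Carlo sampling.
#'
#' @return A `bioid_config` list.
#' @examples
#' cfg <- bioid_config()
#' cfg$spc_min
#' @export
bioid_config <- function(spc_min = 10, prob_min = 0.9, fca_min = 7,
                         r_up = 2, r_down = 1 / r_up, alpha = 0.05,
                         pseudocount = 1, fca_floor = 0.1, prior = 0.5,
                         bg_floor = 0.1, welch = FALSE,
                         use_normalized_spc = FALSE, classify_all = FALSE,
                         adjust_p = FALSE, max_permutations = 500L,
                         seed = NULL) {
  if (spc_min <= 0 || prob_min <= 0 || fca_min <= 0) {
    abort("hit-selection thresholds (spc_min, prob_min, fca_min) must be positive")
  }
  if (prob_min >= 1) abort("`prob_min` must lie in (0, 1)")
  if (r_up <= r_down || r_down <= 0) {
    abort("need 0 < r_down < r_up for the ratio classification thresholds")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (pseudocount <= 0) abort("`pseudocount` must be positive")
  if (fca_floor <= 0 || bg_floor <= 0) abort("floors must be positive")
  if (prior <= 0 || prior >= 1) abort("`prior` must lie in (0, 1)")
  structure(
    list(
      spc_min = spc_min, prob_min = prob_min, fca_min = fca_min,
      r_up = r_up, r_down = r_down, alpha = alpha,
      pseudocount = pseudocount, fca_floor = fca_floor, prior = prior,
      bg_floor = bg_floor, welch = isTRUE(welch),
      use_normalized_spc = isTRUE(use_normalized_spc),
      classify_all = isTRUE(classify_all), adjust_p = isTRUE(adjust_p),
      max_permutations = as.integer(max_permutations),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "bioid_config"
  )
}

#' @export
print.bioid_config <- function(x, ...) {
  cat("<bioid_config>\n")
  cat(sprintf("  hit selection : mean SpC > %g, prob > %g, FC-A > %g\n",
              x$spc_min, x$prob_min, x$fca_min))
  cat(sprintf("  classification: R > %g or R < %g, p < %g (%s t)\n",
              x$r_up, x$r_down, x$alpha,
              if (x$welch) "Welch" else "pooled"))
  cat(sprintf("  pseudocount %g | FC-A floor %g | prior %g | bg floor %g\n",
              x$pseudocount, x$fca_floor, x$prior, x$bg_floor))
  invisible(x)
}

as_bioid_config <- function(config) {
  if (inherits(config, "bioid_config")) return(config)
  if (is.null(config)) return(bioid_config())
  abort("`config` must be created by bioid_config()")
}
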