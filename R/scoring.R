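#' Primary fold change (FC-A) of a prey over control purifications
#'
#' Contaminant-aware fold change in the CRAPome style: the mean spectral
#' count over the bait runs divided by the mean over all negative-control
#' runs, with a small floor on the control mean so that preys never seen
#' in controls receive a finite, large score rather than infinity.
#'
#' @param bait_counts Numeric vector of SpC over the bait-condition runs.
#' @param control_counts Numeric vector of SpC over the control runs.
#' @param floor Positive floor applied to the control mean (default 0.1).
#' @return FC-A, a non-negative scalar; 0 exactly when every bait count
#'   is 0.
#' @examples
#' compute_fca(c(21, 21, 21), c(3, 3, 3))  # 7
#' compute_fca(c(10, 20, 30), c(0, 0, 0))  # 200: zero-control floor
#' @export
compute_fca <- function(bait_counts, control_counts, floor = 0.1) {
  if (!length(bait_counts) || !length(control_counts)) {
    abort("bait and control count vectors must be nonempty")
  }
  if (floor <= 0) abort("`floor` must be positive")
  mean(bait_counts) / max(mean(control_counts), floor)
}

#' Interaction probability from a two-component Poisson model
#'
#' SAINT-style probability that a prey is a true interactor rather than
#' part of the contaminant background. Counts are modelled as Poisson with
#' a background rate estimated from the control runs (floored at `floor`)
#' and a true-interaction rate estimated from the bait runs (floored at
#' the background rate). Each bait replicate contributes the posterior
#' probability of the interaction component under the prior `prior`, and
#' the score is the replicate average. When the bait mean does not exceed
#' the background rate the score is truncated to 0: sub-background counts
#' are never rewarded.
#'
#' @inheritParams compute_fca
#' @param prior Prior probability of a true interaction, in (0, 1).
#' @param floor Positive floor on the background rate (default 0.1).
#' @return Probability in \[0, 1\], invariant under replicate reordering.
#' @examples
#' compute_prob(c(10, 10, 10), c(1, 1, 1))  # ~1
#' compute_prob(c(2, 2, 2), c(2, 2, 2))     # 0: no enrichment over background
#' @export
compute_prob <- function(bait_counts, control_counts, prior = 0.5,
                         floor = 0.1) {
  if (!length(bait_counts) || !length(control_counts)) {
    abort("bait and control count vectors must be nonempty")
  }
  if (floor <= 0) abort("`floor` must be positive")
  if (prior <= 0 || prior >= 1) abort("`prior` must lie in (0, 1)")
  lambda0 <- max(mean(control_counts), floor)
  if (mean(bait_counts) <= lambda0) return(0)
  lambda1 <- mean(bait_counts)
  f1 <- dpois(bait_counts, lambda1)
  f0 <- dpois(bait_counts, lambda0)
  mean(prior * f1 / (prior * f1 + (1 - prior) * f0))
}

#' Score every prey in both bait conditions and select hits
#'
#' Computes, per prey and per bait condition, the mean raw SpC, the FC-A
#' fold change and the two-component Poisson interaction probability
#' against the shared control runs, then applies the three-criterion hit
#' selection: a prey is a high-confidence hit when, within a single bait
#' condition, mean SpC > `spc_min` AND probability > `prob_min` AND
#' FC-A > `fca_min` (strict inequalities; satisfying all three in either
#' condition suffices). All-zero prey rows are reported with scores 0 and
#' are never hits.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param design A [bioid_design()].
#' @param config A [bioid_config()].
#' @return Tibble with one row per prey: `prey_id`, `mean_spc_A`,
#'   `mean_spc_B`, `fca_A`, `fca_B`, `prob_A`, `prob_B`, `is_hit`.
#' @export
score_interactions <- function(counts, design, config = bioid_config()) {
  config <- as_bioid_config(config)
  counts <- validate_count_table(counts, design)
  check_min_replicates(design)
  ctrl <- spc_matrix(counts, runs_of(design, "control"))
  a <- spc_matrix(counts, runs_of(design, "bait_A"))
  b <- spc_matrix(counts, runs_of(design, "bait_B"))
  ctrl_mean <- rowMeans(ctrl)

  score_side <- function(m) {
    bait_mean <- rowMeans(m)
    fca <- bait_mean / pmax(ctrl_mean, config$fca_floor)
    prob <- vapply(seq_len(nrow(m)), function(i) {
      compute_prob(m[i, ], ctrl[i, ], prior = config$prior,
                   floor = config$bg_floor)
    }, numeric(1))
    list(mean = unname(bait_mean), fca = unname(fca), prob = prob)
  }
  sa <- score_side(a)
  sb <- score_side(b)

  scores <- tibble(
    prey_id = counts$prey_id,
    mean_spc_A = sa$mean, mean_spc_B = sb$mean,
    fca_A = sa$fca, fca_B = sb$fca,
    prob_A = sa$prob, prob_B = sb$prob
  )
  zero <- counts$prey_id %in% all_zero_preys(counts)
  scores[zero, c("mean_spc_A", "mean_spc_B", "fca_A", "fca_B",
                 "prob_A", "prob_B")] <- 0
  select_hits(scores, config)
}

#' Apply the three-criterion hit selection to a score table
#'
#' @param scores Tibble as returned by [score_interactions()] (the
#'   `is_hit` column, if present, is recomputed).
#' @param config A [bioid_config()].
#' @return `scores` with a logical `is_hit` column.
#' @export
select_hits <- function(scores, config = bioid_config()) {
  config <- as_bioid_config(config)
  hit_in <- function(m, p, f) {
    m > config$spc_min & p > config$prob_min & f > config$fca_min
  }
  dplyr::mutate(
    as_tibble(scores),
    is_hit = hit_in(.data$mean_spc_A, .data$prob_A, .data$fca_A) |
      hit_in(.data$mean_spc_B, .data$prob_B, .data$fca_B)
  )
}

#' Recovery of previously reported interactors
#'
#' Sensitivity of a screen against a reference list of known interactors:
#' how many of the reference preys were recovered as hits, and what
#' percentage of the reference that represents (rounded to the nearest
#' integer for display, as such rates are conventionally reported).
#'
#' @param hits Character vector of hit prey ids (or a score tibble with
#'   `prey_id` and `is_hit` columns).
#' @param reference Nonempty character vector of known-interactor ids.
#' @return Tibble with `n_recovered`, `n_reference`, `percent`.
#' @examples
#' recovery_rate(paste0("p", 1:10), paste0("p", c(1:7, 20:28)))
#' @export
recovery_rate <- function(hits, reference) {
  if (is.data.frame(hits)) hits <- hits$prey_id[hits$is_hit]
  reference <- unique(as.character(reference))
  if (!length(reference)) abort("`reference` must be nonempty")
  n <- length(intersect(unique(as.character(hits)), reference))
  tibble(
    n_recovered = n,
    n_reference = length(reference),
    percent = round(100 * n / length(reference))
  )
}
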