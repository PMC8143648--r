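#' Normalize spectral counts to the bait abundance of a reference run
#'
#' Between-run differences in bait expression and purification efficiency
#' scale every prey's counts. The classical correction divides each bait
#' run by the ratio of its bait self-count to the bait self-count of the
#' reference run (conventionally wild-type experiment #1), so that after
#' normalization the bait's own row is constant across all bait runs.
#' Control runs are passed through untouched: they play no role in the
#' differential ratio.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param design A [bioid_design()]; its `bait_prey_id` row must be
#'   strictly positive in every bait run.
#' @return Tibble of the same shape with normalized (real-valued) bait-run
#'   columns and a `scale_factors` attribute (named per-run divisors;
#'   1 for control runs).
#' @export
normalize_counts <- function(counts, design) {
  counts <- validate_count_table(counts, design)
  bait_spc <- bait_row_counts(counts, design)
  bruns <- bait_runs_of(design)
  zero_runs <- bruns[bait_spc[bruns] == 0]
  if (length(zero_runs)) {
    abort(paste0("bait self-count is zero in bait run(s): ",
                 paste(zero_runs, collapse = ", "),
                 "; cannot normalize"))
  }
  ref <- reference_run(design)
  s <- setNames(rep(1, nrow(design)), design$run_id)
  s[bruns] <- bait_spc[bruns] / bait_spc[[ref]]
  norm <- counts
  for (r in bruns) norm[[r]] <- counts[[r]] / s[[r]]
  attr(norm, "scale_factors") <- s
  attr(norm, "all_zero") <- attr(counts, "all_zero")
  norm
}

#' Per-prey differential ratio R and t-test between bait conditions
#'
#' For each prey, adds a pseudocount to the normalized SpC of every bait
#' run, log2-transforms, averages within each bait condition to give
#' `L_A` and `L_B`, and forms the ratio `R = 2^(L_A - L_B)`. Statistical
#' significance of the condition difference comes from a two-sample
#' t-test on the per-run log2 values (pooled variance by default,
#' `df = n_A + n_B - 2`; Welch with `welch = TRUE`). When both sample
#' variances are zero (common with small integer counts) the test is
#' degenerate: p is defined as 1 for equal means and 0 otherwise, with a
#' warning, so the effect-size gate on `R` stays decisive.
#'
#' @param norm Normalized count tibble from [normalize_counts()].
#' @param design A [bioid_design()] with at least two replicates per bait
#'   condition.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param welch Use Welch's t-test instead of pooled variance.
#' @return Tibble with `prey_id`, `L_A`, `L_B`, `R`, `t_stat`, `p`.
#' @examples
#' # three runs per condition with normalized counts (3,7,15) vs (0,1,3)
#' # give log2 values (2,3,4) vs (0,1,2): R = 4, t = 2.449, p = 0.0705
#' @export
compute_ratio_profile <- function(norm, design, pseudocount = 1,
                                  welch = FALSE) {
  a_runs <- runs_of(design, "bait_A")
  b_runs <- runs_of(design, "bait_B")
  if (length(a_runs) < 2 || length(b_runs) < 2) {
    abort("need at least 2 replicates in each bait condition for the t-test")
  }
  la <- log2(spc_matrix(norm, a_runs) + pseudocount)
  lb <- log2(spc_matrix(norm, b_runs) + pseudocount)
  n_a <- ncol(la); n_b <- ncol(lb)
  m_a <- rowMeans(la); m_b <- rowMeans(lb)
  v_a <- rowSums((la - m_a)^2) / (n_a - 1)
  v_b <- rowSums((lb - m_b)^2) / (n_b - 1)

  if (welch) {
    se2 <- v_a / n_a + v_b / n_b
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    se2 <- sp2 * (1 / n_a + 1 / n_b)
    df <- rep(n_a + n_b - 2, length(se2))
  }
  t_stat <- (m_a - m_b) / sqrt(se2)
  p <- 2 * pt(-abs(t_stat), df)

  degenerate <- se2 == 0
  if (any(degenerate)) {
    warn(sprintf(
      "%d prey(s) had zero variance in both conditions; p set to 0/1 by mean equality",
      sum(degenerate)))
    eq <- degenerate & m_a == m_b
    ne <- degenerate & m_a != m_b
    t_stat[eq] <- 0; p[eq] <- 1
    t_stat[ne] <- sign(m_a - m_b)[ne] * Inf; p[ne] <- 0
  }

  tibble(
    prey_id = norm$prey_id,
    L_A = unname(m_a), L_B = unname(m_b), R = unname(2^(m_a - m_b)),
    t_stat = unname(t_stat), p = unname(p)
  )
}

#' Classify preys as condition-preferred or neutral
#'
#' Three-way classification of differential profiles: `A_preferred` when
#' `R > r_up` and `p < alpha`, `B_preferred` when `R < r_down` and
#' `p < alpha`, otherwise `neutral`. All inequalities strict, so boundary
#' values (e.g. `R` exactly 2) are neutral.
#'
#' @param profiles Tibble with `R` and `p` columns (e.g. from
#'   [compute_ratio_profile()]).
#' @param config A [bioid_config()]. With `adjust_p = TRUE` the p-values
#'   are Benjamini-Hochberg adjusted before gating.
#' @return `profiles` with a `klass` factor column
#'   (`A_preferred`/`B_preferred`/`neutral`).
#' @export
classify_preys <- function(profiles, config = bioid_config()) {
  config <- as_bioid_config(config)
  p <- if (config$adjust_p) stats::p.adjust(profiles$p, "BH") else profiles$p
  klass <- dplyr::case_when(
    profiles$R > config$r_up & p < config$alpha ~ "A_preferred",
    profiles$R < config$r_down & p < config$alpha ~ "B_preferred",
    .default = "neutral"
  )
  dplyr::mutate(as_tibble(profiles),
                klass = factor(klass, levels = class_levels()))
}

class_levels <- function() c("A_preferred", "B_preferred", "neutral")

#' Permutation estimate of the classification false discovery rate
#'
#' Reassigns the two bait-condition labels across the bait runs in every
#' possible balanced way (C(6,3) = 20 for triplicates), excluding the
#' observed labelling and its mirror image (the mirror reproduces the
#' observed discovery total exactly, by the reciprocity of `R`), reruns
#' the ratio/t-test/classification on each relabelling, and compares the
#' mean permuted discovery count (A-preferred + B-preferred) with the
#' observed one: `FDR = mean permuted / observed`, clipped to \[0, 1\].
#' Designs with more than `config$max_permutations` admissible
#' relabellings are Monte-Carlo sampled with the config seed.
#'
#' @param norm Normalized counts from [normalize_counts()].
#' @param design A [bioid_design()] with at least 2 runs per bait side.
#' @param config A [bioid_config()].
#' @param prey_ids Optional subset of preys (normally the selected hits)
#'   over which discoveries are counted.
#' @return List with `fdr` (0 when neither the observed labelling nor any
#'   permutation discovers anything; NA — undefined, not zero — when
#'   permutations discover but the observed labelling does not), `observed` discovery count,
#'   and `perm_counts`, the per-permutation discovery counts.
#' @export
estimate_fdr_permutation <- function(norm, design, config = bioid_config(),
                                     prey_ids = NULL) {
  config <- as_bioid_config(config)
  a_runs <- runs_of(design, "bait_A")
  b_runs <- runs_of(design, "bait_B")
  if (length(a_runs) < 2 || length(b_runs) < 2) {
    abort("permutation FDR needs at least 2 runs per bait condition")
  }
  if (!is.null(prey_ids)) norm <- norm[norm$prey_id %in% prey_ids, ]
  bruns <- c(a_runs, b_runs)
  n_a <- length(a_runs)

  count_discoveries <- function(a_set) {
    d2 <- design
    idx <- d2$run_id %in% bruns
    d2$condition[idx] <- ifelse(d2$run_id[idx] %in% a_set,
                                "bait_A", "bait_B")
    prof <- suppressWarnings(
      compute_ratio_profile(norm, d2, pseudocount = config$pseudocount,
                            welch = config$welch))
    sum(classify_preys(prof, config)$klass != "neutral")
  }

  observed <- count_discoveries(a_runs)

  assignments <- utils::combn(bruns, n_a, simplify = FALSE)
  same_set <- function(x, y) setequal(x, y)
  keep <- !vapply(assignments, function(s) {
    same_set(s, a_runs) || same_set(s, b_runs)
  }, logical(1))
  assignments <- assignments[keep]
  if (length(assignments) > config$max_permutations) {
    if (!is.null(config$seed)) {
      assignments <- withr::with_seed(
        config$seed, sample(assignments, config$max_permutations))
    } else {
      assignments <- sample(assignments, config$max_permutations)
    }
  }
  perm_counts <- vapply(assignments, count_discoveries, numeric(1))
  list(fdr = fdr_from_counts(observed, perm_counts), observed = observed,
       perm_counts = perm_counts)
}

# ratio of mean permuted discoveries to observed discoveries, clipped to
# [0,1]; degenerate cases: nothing discovered anywhere -> 0 (trivially no
# false discoveries), permuted discoveries without observed ones -> NA
# (the ratio is undefined, not zero)
fdr_from_counts <- function(observed, perm_counts) {
  if (observed > 0) return(min(max(mean(perm_counts) / observed, 0), 1))
  if (!length(perm_counts) || mean(perm_counts) == 0) return(0)
  NA_real_
}
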