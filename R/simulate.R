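#' Simulate a triplicate BioID experiment with planted ground truth
#'
#' Generative model of the canonical BioID study design: three
#' purifications each of two bait conditions (e.g. a wild-type and a
#' trafficking-mutant form of one bait) and three negative-control
#' purifications sharing one contaminant background. Every prey draws a
#' per-prey background contamination rate from a gamma distribution; true
#' interactors are boosted multiplicatively over their background rate,
#' and condition-preferred interactors split a differential `effect`
#' symmetrically on the log scale, so `mean_A / mean_B` equals `effect`
#' (A-preferred), `1/effect` (B-preferred) or 1 (shared / background).
#' Bait-abundance drift is injected multiplicatively into the bait-run
#' means via the per-run bait self-counts, so that normalization to the
#' reference run is exactly the correct inverse transform. Counts are
#' negative binomial with `variance = mu + dispersion * mu^2` (Poisson at
#' dispersion 0); rates below 0.01 are clamped to 0.01 so evidence-free
#' all-zero preys stay rare.
#'
#' @param n_prey Number of simulated preys (the bait's own row is added
#'   on top).
#' @param frac_A_pref,frac_B_pref,frac_shared Fractions of preys planted
#'   as A-preferred, B-preferred and shared (condition-neutral) true
#'   interactors; must sum to at most 1, the remainder are
#'   background-only contaminants.
#' @param background_shape,background_scale Gamma parameters of the
#'   per-prey contaminant rate (default mean 3 SpC).
#' @param interactor_boost Multiplicative enrichment of true interactors
#'   over their own background rate (default 10, i.e. mean ~30 SpC).
#' @param effect Ratio of the two condition means for preferred preys
#'   (default 8).
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param bait_self_counts Named (or positional, bait-run order: A then
#'   B replicates) positive integers used as the bait's own SpC per bait
#'   run; unequal values exercise the normalization.
#' @param bait_prey_id Row id of the bait protein.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `counts` (count tibble), `design`
#'   ([bioid_design()]) and `truth` (tibble: `prey_id`, `true_class` in
#'   A_preferred/B_preferred/shared/background, `background_rate`,
#'   `mean_A`, `mean_B`).
#' @examples
#' sim <- simulate_bioid(n_prey = 50, seed = 1)
#' dplyr::count(sim$truth, true_class)
#' @export
simulate_bioid <- function(n_prey = 1000,
                           frac_A_pref = 0.05, frac_B_pref = 0.05,
                           frac_shared = 0.10,
                           background_shape = 6, background_scale = 0.5,
                           interactor_boost = 10, effect = 8,
                           nb_dispersion = 0.3,
                           bait_self_counts = c(A1 = 100, A2 = 80, A3 = 120,
                                                B1 = 90, B2 = 110, B3 = 70),
                           bait_prey_id = "BAIT",
                           seed = NULL) {
  fracs <- c(frac_A_pref, frac_B_pref, frac_shared)
  if (any(fracs < 0) || sum(fracs) > 1) {
    abort("class fractions must be non-negative and sum to at most 1")
  }
  if (any(bait_self_counts <= 0) || length(bait_self_counts) != 6) {
    abort("`bait_self_counts` must be 6 positive integers (3 per bait condition)")
  }
  if (effect <= 0 || interactor_boost <= 0) {
    abort("`effect` and `interactor_boost` must be positive")
  }
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")

  design <- bioid_design(
    tibble(
      run_id = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3"),
      bait_id = rep(c("bait_wt", "bait_mut", "ctrl_bait"), each = 3),
      condition = rep(c("bait_A", "bait_B", "control"), each = 3),
      replicate = rep(1:3, 3)
    ),
    reference_run = "A1", bait_prey_id = bait_prey_id
  )
  bruns <- bait_runs_of(design)
  self <- setNames(as.integer(bait_self_counts), bruns)
  drift <- self / self[[reference_run(design)]]

  gen <- function() {
    n_cls <- c(
      A_preferred = round(n_prey * frac_A_pref),
      B_preferred = round(n_prey * frac_B_pref),
      shared = round(n_prey * frac_shared)
    )
    n_bg <- n_prey - sum(n_cls)
    true_class <- rep(c(names(n_cls), "background"), c(n_cls, n_bg))
    bg_rate <- rgamma(n_prey, shape = background_shape,
                      scale = background_scale)
    base <- ifelse(true_class == "background", bg_rate,
                   bg_rate * interactor_boost)
    half <- sqrt(effect)
    mean_a <- base * ifelse(true_class == "A_preferred", half,
                            ifelse(true_class == "B_preferred", 1 / half, 1))
    mean_b <- base * ifelse(true_class == "B_preferred", half,
                            ifelse(true_class == "A_preferred", 1 / half, 1))

    draw <- function(mu) {
      mu <- pmax(mu, 0.01)
      if (nb_dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    }
    prey_id <- sprintf("prey_%04d", seq_len(n_prey))
    cols <- c(
      lapply(setNames(runs_of(design, "bait_A"), runs_of(design, "bait_A")),
             function(r) draw(mean_a * drift[[r]])),
      lapply(setNames(runs_of(design, "bait_B"), runs_of(design, "bait_B")),
             function(r) draw(mean_b * drift[[r]])),
      lapply(setNames(runs_of(design, "control"), runs_of(design, "control")),
             function(r) draw(bg_rate))
    )
    counts <- tibble(prey_id = prey_id, !!!cols[design$run_id])
    # bait's own row: self-counts in bait runs, absent from the control bait
    counts <- dplyr::bind_rows(
      tibble(prey_id = bait_prey_id,
             !!!as.list(c(self, C1 = 0L, C2 = 0L, C3 = 0L))[design$run_id]),
      counts
    )
    truth <- tibble(
      prey_id = prey_id,
      true_class = factor(true_class, levels = c("A_preferred",
                                                 "B_preferred", "shared",
                                                 "background")),
      background_rate = bg_rate, mean_A = mean_a, mean_B = mean_b
    )
    list(counts = validate_count_table(counts, design), design = design,
         truth = truth)
  }

  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Write a simulated experiment to disk
#'
#' Writes the count table, design table and ground-truth table as TSVs —
#' the same formats the pipeline reads back.
#'
#' @param sim List from [simulate_bioid()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(sim$counts, paths[["counts"]])
  write_design_table(sim$design, paths[["design"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
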