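#' Run the full differential BioID profiling pipeline
#'
#' End-to-end orchestration: score every prey in both bait conditions
#' against the controls, select high-confidence hits, normalize the bait
#' runs to the reference run's bait abundance, compute the per-prey ratio
#' `R` and t-test, classify the hits as A-preferred / B-preferred /
#' neutral, and estimate the classification FDR by label permutation.
#' Every input prey appears exactly once in the result, and the three
#' class counts partition the hit set.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param design A [bioid_design()].
#' @param config A [bioid_config()].
#' @param permutation_fdr Set `FALSE` to skip the permutation FDR
#'   (reported as NA).
#' @return A `bioid_profile` object: list with `results` (per-prey
#'   tibble), `summary` (one-row tibble: `n_prey`, `n_hits`,
#'   `n_A_preferred`, `n_B_preferred`, `n_neutral`, `fdr`), `counts`,
#'   `normalized`, `design`, `config` and `perm` (the permutation
#'   discovery counts). Use [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] on it.
#' @export
run_profile <- function(counts, design, config = bioid_config(),
                        permutation_fdr = TRUE) {
  config <- as_bioid_config(config)
  counts <- validate_count_table(counts, design)
  scores <- score_interactions(counts, design, config)
  norm <- normalize_counts(counts, design)
  profiles <- compute_ratio_profile(norm, design,
                                    pseudocount = config$pseudocount,
                                    welch = config$welch)
  profiles <- classify_preys(profiles, config)

  results <- dplyr::left_join(scores, profiles, by = "prey_id")
  # classification applies to selected hits unless classify_all is set;
  # evidence-free (all-zero) preys are always neutral with zero scores
  if (!config$classify_all) {
    results$klass[!results$is_hit] <- "neutral"
  }
  zero <- results$prey_id %in% all_zero_preys(counts)
  results$klass[zero] <- "neutral"

  hit_ids <- results$prey_id[results$is_hit]
  perm <- list(fdr = NA_real_, observed = NA_real_, perm_counts = numeric(0))
  if (isTRUE(permutation_fdr) && length(hit_ids)) {
    perm <- estimate_fdr_permutation(norm, design, config,
                                     prey_ids = hit_ids)
  }

  hit_klass <- results$klass[results$is_hit]
  summary <- tibble(
    n_prey = nrow(results),
    n_hits = length(hit_ids),
    n_A_preferred = sum(hit_klass == "A_preferred"),
    n_B_preferred = sum(hit_klass == "B_preferred"),
    n_neutral = sum(hit_klass == "neutral"),
    fdr = perm$fdr
  )

  structure(
    list(results = results, summary = summary, counts = counts,
         normalized = norm, design = design, config = config,
         perm = perm),
    class = "bioid_profile"
  )
}

#' @export
print.bioid_profile <- function(x, ...) {
  s <- x$summary
  cat("<bioid_profile>\n")
  cat(sprintf("  %d preys, %d high-confidence hits\n", s$n_prey, s$n_hits))
  cat(sprintf("  n_hits = n_A_pref + n_B_pref + n_neutral : %d = %d + %d + %d\n",
              s$n_hits, s$n_A_preferred, s$n_B_preferred, s$n_neutral))
  cat(sprintf("  permutation FDR estimate: %s\n",
              ifelse(is.na(s$fdr), "undefined (no discoveries)",
                     format(s$fdr, digits = 3))))
  invisible(x)
}

#' Tidy the per-prey results of a profile
#'
#' @param x A `bioid_profile`.
#' @param ... Unused.
#' @return Per-prey results tibble (scores, `L_A`, `L_B`, `R`, `t_stat`,
#'   `p`, `klass`, `is_hit`).
#' @method tidy bioid_profile
#' @export
tidy.bioid_profile <- function(x, ...) x$results

#' One-row summary of a profile
#'
#' @param x A `bioid_profile`.
#' @param ... Unused.
#' @return One-row tibble: `n_prey`, `n_hits`, `n_A_preferred`,
#'   `n_B_preferred`, `n_neutral`, `fdr`.
#' @method glance bioid_profile
#' @export
glance.bioid_profile <- function(x, ...) x$summary

#' Scatter plot of the two bait-condition profiles
#'
#' The classical differential-interactome view: the average
#' log2-transformed normalized SpC of condition B on the x axis against
#' condition A on the y axis, one point per prey, coloured by class.
#'
#' @param object A `bioid_profile`.
#' @param hits_only Plot only the selected hits (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bioid_profile
#' @export
autoplot.bioid_profile <- function(object, hits_only = TRUE, ...) {
  d <- object$results
  if (hits_only) d <- d[d$is_hit, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$L_B, y = .data$L_A,
                                  colour = .data$klass)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      A_preferred = "#1b9e77", B_preferred = "#d95f02",
      neutral = "grey40"), drop = FALSE) +
    ggplot2::labs(
      x = "mean log2(normalized SpC + 1), condition B",
      y = "mean log2(normalized SpC + 1), condition A",
      colour = "class") +
    ggplot2::theme_minimal()
}

#' Write the full results table
#'
#' One row per prey, mirroring the conventional supplementary-table
#' layout: raw SpC per run, normalized SpC per run (one decimal,
#' half-up), log2(normalized + pseudocount) per run, the condition
#' averages `L_A`/`L_B`, `R`, `p`, class, and the interaction scores.
#' Header comment lines record the configuration values.
#'
#' @param profile A `bioid_profile` from [run_profile()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(profile, path) {
  stopifnot(inherits(profile, "bioid_profile"))
  design <- profile$design
  cfg <- profile$config
  runs <- design$run_id
  bruns <- bait_runs_of(design)

  raw <- as_tibble(profile$counts)
  names(raw)[-1] <- paste0("raw_", runs)
  norm <- as_tibble(profile$normalized)[c("prey_id", bruns)]
  norm[bruns] <- lapply(norm[bruns], round_half_up, digits = 1)
  names(norm)[-1] <- paste0("norm_", bruns)
  logn <- as_tibble(profile$normalized)[c("prey_id", bruns)]
  logn[bruns] <- lapply(logn[bruns],
                        function(x) round(log2(x + cfg$pseudocount), 4))
  names(logn)[-1] <- paste0("log2_", bruns)

  out <- raw |>
    dplyr::left_join(norm, by = "prey_id") |>
    dplyr::left_join(logn, by = "prey_id") |>
    dplyr::left_join(profile$results, by = "prey_id")
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 4))

  header <- c(
    "# bioidr results",
    sprintf("# spc_min=%g prob_min=%g fca_min=%g", cfg$spc_min,
            cfg$prob_min, cfg$fca_min),
    sprintf("# r_up=%g r_down=%g alpha=%g pseudocount=%g", cfg$r_up,
            cfg$r_down, cfg$alpha, cfg$pseudocount),
    sprintf("# fca_floor=%g prior=%g bg_floor=%g welch=%s", cfg$fca_floor,
            cfg$prior, cfg$bg_floor, cfg$welch),
    sprintf("# reference_run=%s bait_prey_id=%s", reference_run(design),
            bait_prey_id(design))
  )
  writeLines(header, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return Results tibble (header comments dropped).
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    prey_id = readr::col_character(),
    klass = readr::col_character(),
    is_hit = readr::col_logical(),
    .default = readr::col_double()
  ))
}

# round half away from zero (base round() is half-to-even); printed
# normalized SpC follow the conventional half-up reading of one decimal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
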