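test_that("bait-abundance normalization inverts per-run scale factors", {
  design <- tiny_design()

  # equal bait self-counts: identity
  flat <- tiny_counts(list(BAIT = flat_bait_row(100),
                           p1 = c(5, 6, 7, 1, 2, 3, 0, 0, 1)))
  norm <- normalize_counts(flat, design)
  expect_equal(unattr(norm[-1]), unattr(flat[-1]))
  expect_equal(unname(attr(norm, "scale_factors")), rep(1, 9))

  # worked scale factors: run bait 200 vs reference 100 halves the cell;
  # run bait 50 doubles it
  counts <- tiny_counts(list(
    BAIT = c(100, 200, 50, 100, 100, 100, 0, 0, 0),
    p1   = c(10, 10, 7, 4, 4, 4, 2, 2, 2)
  ))
  norm <- normalize_counts(counts, design)
  expect_equal(norm$A2[norm$prey_id == "p1"], 5)
  expect_equal(norm$A3[norm$prey_id == "p1"], 14)
  # bait row constant across bait runs, equal to reference-run SpC
  bait_row <- unlist(norm[norm$prey_id == "BAIT",
                          c("A1", "A2", "A3", "B1", "B2", "B3")])
  expect_equal(unname(bait_row), rep(100, 6))
  # control runs untouched
  expect_equal(norm$C1, counts$C1)

  # zero bait self-count in a bait run is a hard error naming the run
  broken <- tiny_counts(list(BAIT = c(100, 0, 100, 100, 100, 100, 0, 0, 0),
                             p1 = rep(1L, 9)))
  expect_error(normalize_counts(broken, design), "A2")
})

test_that("normalization is invariant to scaling a bait run's counts", {
  design <- tiny_design()
  withr::local_seed(21)
  counts <- random_counts(20, design)
  norm <- normalize_counts(counts, design)

  # scaling a non-reference bait run (bait row included) cancels exactly;
  # the reference run instead sets the global scale of the whole matrix
  scaled <- counts
  scaled$A2 <- scaled$A2 * 3L
  norm2 <- normalize_counts(scaled, design)
  expect_equal(unattr(norm2[-1]), unattr(norm[-1]))

  prof1 <- suppressWarnings(compute_ratio_profile(norm, design))
  prof2 <- suppressWarnings(compute_ratio_profile(norm2, design))
  expect_equal(prof1, prof2)
})

test_that("ratio profile reproduces exact worked examples", {
  design <- tiny_design()
  counts <- tiny_counts(list(
    BAIT = flat_bait_row(),
    exact = c(7, 7, 7, 1, 1, 1, 0, 0, 0),   # log2 of 8 vs 2
    equal = c(4, 9, 2, 4, 9, 2, 0, 0, 0),
    mixed = c(3, 7, 15, 0, 1, 3, 0, 0, 0)   # log2 (2,3,4) vs (0,1,2)
  ))
  norm <- normalize_counts(counts, design)
  expect_warning(compute_ratio_profile(norm, design), "zero variance")
  prof <- suppressWarnings(compute_ratio_profile(norm, design))
  prof <- split(as.data.frame(prof), prof$prey_id)

  expect_equal(prof$exact$L_A, 3)
  expect_equal(prof$exact$L_B, 1)
  expect_equal(prof$exact$R, 4)
  expect_equal(prof$exact$p, 0)  # zero variance, unequal means

  expect_equal(prof$equal$R, 1)
  expect_equal(prof$equal$t_stat, 0)
  expect_equal(prof$equal$p, 1)

  expect_equal(prof$mixed$L_A, 3)
  expect_equal(prof$mixed$L_B, 1)
  expect_equal(prof$mixed$R, 4)
  expect_equal(prof$mixed$t_stat, 2.449, tolerance = 1e-3)
  expect_equal(prof$mixed$p, 0.0705, tolerance = 1e-3)
})

test_that("pooled and Welch t match the textbook oracle to 1e-12", {
  design <- tiny_design()
  withr::local_seed(31)
  counts <- random_counts(40, design)
  norm <- normalize_counts(counts, design)
  for (welch in c(FALSE, TRUE)) {
    prof <- suppressWarnings(
      compute_ratio_profile(norm, design, welch = welch))
    la <- log2(as.matrix(norm[c("A1", "A2", "A3")]) + 1)
    lb <- log2(as.matrix(norm[c("B1", "B2", "B3")]) + 1)
    for (i in seq_len(nrow(norm))) {
      if (var(la[i, ]) == 0 && var(lb[i, ]) == 0) next
      tt <- stats::t.test(la[i, ], lb[i, ], var.equal = !welch)
      expect_equal(prof$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(prof$p[i], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("swapping conditions is a reciprocity on R and preserves p", {
  design <- tiny_design()
  withr::local_seed(41)
  counts <- random_counts(30, design)
  norm <- normalize_counts(counts, design)
  prof <- suppressWarnings(compute_ratio_profile(norm, design))
  swapped <- suppressWarnings(
    compute_ratio_profile(norm, swap_conditions_for_test(design)))
  expect_equal(swapped$R, 1 / prof$R)
  expect_equal(swapped$t_stat, -prof$t_stat)
  expect_equal(swapped$p, prof$p)
})

test_that("classification gates strictly on R and p", {
  cfg <- bioid_config()
  classify1 <- function(R, p) {
    as.character(classify_preys(tibble::tibble(R = R, p = p), cfg)$klass)
  }
  # the published wild-type-preferred exemplar
  expect_equal(classify1(56.0, 8e-4), "A_preferred")
  expect_equal(classify1(2.0, 0.001), "neutral")   # boundary R
  expect_equal(classify1(0.5, 0.001), "neutral")   # boundary R, low side
  expect_equal(classify1(0.3, 0.01), "B_preferred")
  expect_equal(classify1(3.0, 0.05), "neutral")    # boundary p
  expect_equal(classify1(1.2, 0.001), "neutral")
})

test_that("permutation FDR handles degenerate and null inputs", {
  design <- tiny_design()

  # identical bait-run columns: no permutation can discover anything
  counts <- tiny_counts(list(
    BAIT = flat_bait_row(),
    p1 = c(rep(12L, 6), 0, 0, 0),
    p2 = c(rep(30L, 6), 1, 1, 1)
  ))
  norm <- normalize_counts(counts, design)
  out <- estimate_fdr_permutation(norm, design,
                                  prey_ids = c("p1", "p2"))
  expect_equal(length(out$perm_counts), 18)
  expect_equal(out$observed, 0)
  expect_equal(out$fdr, 0)
  expect_true(all(out$perm_counts == 0))

  # the estimate is mean(permuted)/observed clipped to [0,1]; with no
  # observed discoveries it is undefined (NA), never silently zero,
  # unless the permutations discover nothing either
  expect_equal(bioidr:::fdr_from_counts(10, c(1, 2, 0)), 0.1)
  expect_equal(bioidr:::fdr_from_counts(2, rep(5, 18)), 1)
  expect_true(is.na(bioidr:::fdr_from_counts(0, c(0, 3, 0))))
  expect_equal(bioidr:::fdr_from_counts(0, rep(0, 18)), 0)
})

test_that("run_profile partitions hits and respects label swapping", {
  sim <- simulate_bioid(n_prey = 200, seed = 9)
  cfg <- bioid_config(seed = 9)
  prof <- suppressWarnings(run_profile(sim$counts, sim$design, cfg))
  s <- glance(prof)
  expect_equal(s$n_hits, s$n_A_preferred + s$n_B_preferred + s$n_neutral)
  expect_equal(nrow(tidy(prof)), nrow(sim$counts))
  expect_equal(sort(tidy(prof)$prey_id), sort(sim$counts$prey_id))

  swapped_design <- swap_conditions_for_test(sim$design)
  prof2 <- suppressWarnings(run_profile(sim$counts, swapped_design, cfg))
  s2 <- glance(prof2)
  expect_equal(s2$n_A_preferred, s$n_B_preferred)
  expect_equal(s2$n_B_preferred, s$n_A_preferred)
  expect_equal(s2$n_hits, s$n_hits)

  # no planted effects: preferred calls are rare nominal false positives
  null_sim <- simulate_bioid(n_prey = 300, frac_A_pref = 0, frac_B_pref = 0,
                             frac_shared = 0.3, seed = 13)
  null_prof <- suppressWarnings(
    run_profile(null_sim$counts, null_sim$design, bioid_config(seed = 13),
                permutation_fdr = FALSE))
  ns <- glance(null_prof)
  expect_lt(ns$n_A_preferred + ns$n_B_preferred, 0.2 * ns$n_hits)
})

test_that("plot and summary accessors expose the fitted profile", {
  sim <- simulate_bioid(n_prey = 60, seed = 3)
  prof <- suppressWarnings(
    run_profile(sim$counts, sim$design, permutation_fdr = FALSE))
  expect_s3_class(autoplot(prof), "ggplot")
  expect_s3_class(tidy(prof), "tbl_df")
  expect_named(glance(prof), c("n_prey", "n_hits", "n_A_preferred",
                               "n_B_preferred", "n_neutral", "fdr"))
  expect_output(print(prof), "n_hits = n_A_pref")
})
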