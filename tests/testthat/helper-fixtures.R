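# tiny triplicate design + count fixtures shared across tests

tiny_design <- function(reference_run = "A1", bait_prey_id = "BAIT") {
  bioid_design(
    tibble::tibble(
      run_id = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3"),
      bait_id = rep(c("wt", "mut", "ctrl"), each = 3),
      condition = rep(c("bait_A", "bait_B", "control"), each = 3),
      replicate = rep(1:3, 3)
    ),
    reference_run = reference_run, bait_prey_id = bait_prey_id
  )
}

# counts: named list prey_id -> length-9 vector in run order A1..C3
tiny_counts <- function(rows, design = tiny_design()) {
  m <- do.call(rbind, rows)
  counts <- tibble::as_tibble(m, .name_repair = ~design$run_id)
  counts <- dplyr::bind_cols(tibble::tibble(prey_id = names(rows)), counts)
  validate_count_table(counts, design)
}

# constant-bait fixture: normalization is the identity
flat_bait_row <- function(spc = 100) {
  c(rep(spc, 6), 0, 0, 0)
}

random_counts <- function(n_prey, design = tiny_design(), max_count = 50) {
  rows <- c(
    list(BAIT = flat_bait_row(sample(50:150, 1))),
    setNames(
      lapply(seq_len(n_prey),
             function(i) sample.int(max_count + 1, 9, replace = TRUE) - 1L),
      sprintf("p%03d", seq_len(n_prey))
    )
  )
  tiny_counts(rows, design)
}

# independent log-odds posterior for the two-component Poisson model
oracle_prob <- function(bait, ctrl, prior = 0.5, floor = 0.1) {
  lambda0 <- max(mean(ctrl), floor)
  if (mean(bait) <= lambda0) return(0)
  lambda1 <- mean(bait)
  post <- vapply(bait, function(x) {
    log_odds <- log((1 - prior) / prior) + x * log(lambda0 / lambda1) +
      (lambda1 - lambda0)
    1 / (1 + exp(log_odds))
  }, numeric(1))
  mean(post)
}

# brute-force hypergeometric upper tail via choose()
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exchange the two bait-condition labels, keeping runs and reference fixed
swap_conditions_for_test <- function(design) {
  runs <- tibble::as_tibble(design)
  runs$condition <- c(bait_A = "bait_B", bait_B = "bait_A",
                      control = "control")[runs$condition]
  bioid_design(runs, reference_run = attr(design, "reference_run"),
               bait_prey_id = attr(design, "bait_prey_id"))
}

# drop non-structural attributes (scale factors, zero-row flags) so that
# value comparisons see only the cells
unattr <- function(x) {
  as.data.frame(lapply(as.data.frame(x), function(col) `attributes<-`(col, NULL)),
                check.names = FALSE)
}
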