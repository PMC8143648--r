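#' Experiment design for a BioID screen
#'
#' Describes which mass-spectrometry run belongs to which bait and
#' condition. The canonical layout is triplicate purifications of two bait
#' conditions (e.g. a wild-type and a mutant form of the same bait) plus
#' triplicate negative-control purifications of an unrelated control bait,
#' whose data supply the contaminant background for scoring.
#'
#' @param runs Data frame with columns `run_id`, `bait_id`, `condition`
#'   (one of `"bait_A"`, `"bait_B"`, `"control"`) and `replicate`
#'   (positive integer).
#' @param reference_run `run_id` of the run all bait runs are normalized
#'   to; must be a bait (non-control) run. Convention: bait-A replicate 1
#'   (the wild-type experiment #1).
#' @param bait_prey_id Row identifier of the bait protein itself inside
#'   the count matrix; its self-counts drive the normalization.
#'
#' @return A `bioid_design` tibble with attributes `reference_run` and
#'   `bait_prey_id`.
#' @examples
#' design <- bioid_design(
#'   tibble::tibble(
#'     run_id    = c("A1", "A2", "B1", "B2", "C1", "C2"),
#'     bait_id   = c("KIR", "KIR", "KIRmut", "KIRmut", "TM", "TM"),
#'     condition = rep(c("bait_A", "bait_B", "control"), each = 2),
#'     replicate = rep(1:2, 3)
#'   ),
#'   reference_run = "A1", bait_prey_id = "KIR"
#' )
#' @export
bioid_design <- function(runs, reference_run, bait_prey_id) {
  runs <- as_tibble(runs)
  needed <- c("run_id", "bait_id", "condition", "replicate")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols)) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  runs <- runs[needed]
  runs$run_id <- as.character(runs$run_id)
  runs$bait_id <- as.character(runs$bait_id)
  runs$condition <- as.character(runs$condition)
  runs$replicate <- as.integer(runs$replicate)
  if (anyDuplicated(runs$run_id)) {
    abort(paste0("duplicate run_id(s): ",
                 paste(unique(runs$run_id[duplicated(runs$run_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(runs$condition), c("bait_A", "bait_B", "control"))
  if (length(bad)) {
    abort(paste0("unknown condition(s): ", paste(bad, collapse = ", "),
                 ' (use "bait_A", "bait_B" or "control")'))
  }
  if (any(is.na(runs$replicate)) || any(runs$replicate < 1)) {
    abort("`replicate` must be a positive integer")
  }
  if (!reference_run %in% runs$run_id) {
    abort(sprintf("reference_run '%s' is not a run in the design", reference_run))
  }
  ref_cond <- runs$condition[runs$run_id == reference_run]
  if (ref_cond == "control") {
    abort("reference_run must be a bait run, not a control run")
  }
  structure(runs,
            reference_run = as.character(reference_run),
            bait_prey_id = as.character(bait_prey_id),
            class = c("bioid_design", class(runs)))
}

#' Read a run design table
#'
#' Reads a tab-separated design table with columns `run_id`, `bait_id`,
#' `condition`, `replicate`.
#'
#' @inheritParams bioid_design
#' @param path Path to the TSV file.
#' @return A [bioid_design()] tibble.
#' @export
read_design_table <- function(path, reference_run, bait_prey_id) {
  runs <- readr::read_tsv(path, col_types = readr::cols(
    run_id = readr::col_character(),
    bait_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  bioid_design(runs, reference_run, bait_prey_id)
}

#' Write a run design table
#'
#' @param design A [bioid_design()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  readr::write_tsv(as_tibble(design), path)
  invisible(path)
}

reference_run <- function(design) attr(design, "reference_run")
bait_prey_id <- function(design) attr(design, "bait_prey_id")

runs_of <- function(design, condition) {
  design$run_id[design$condition %in% condition]
}

bait_runs_of <- function(design) {
  design$run_id[design$condition != "control"]
}

# swap the two bait condition labels (used by symmetry properties and the
# permutation machinery); the reference run and scale factors are untouched
swap_conditions <- function(design) {
  cond <- design$condition
  design$condition <- dplyr::case_match(cond,
    "bait_A" ~ "bait_B", "bait_B" ~ "bait_A", .default = cond)
  design
}

check_min_replicates <- function(design, n = 2L) {
  counts <- table(factor(design$condition,
                         levels = c("bait_A", "bait_B", "control")))
  low <- names(counts)[counts < n]
  if (length(low)) {
    abort(paste0("need at least ", n, " runs per condition; too few in: ",
                 paste(low, collapse = ", ")))
  }
  invisible(design)
}
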