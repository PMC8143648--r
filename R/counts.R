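#' Read a spectral-count table
#'
#' Reads a tab-separated prey-by-run table of spectral counts (SpC). The
#' first column holds the prey identifier (opaque string); every remaining
#' column must correspond to exactly one run in the design. Cells must be
#' non-negative integers. Prey rows that are zero in every run carry no
#' evidence; they are retained (so the output row set equals the input row
#' set) but flagged via the `"all_zero"` attribute and excluded from
#' scoring and differential statistics downstream.
#'
#' @param path Path to the TSV file (header row required).
#' @param design A [bioid_design()]; the header must contain all of its
#'   run ids and no other data columns.
#' @return A validated count tibble: column `prey_id` then one integer
#'   column per run, in design order, with attribute `all_zero`.
#' @export
read_count_table <- function(path, design) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            name_repair = "minimal")
  if (ncol(counts) < 2) abort("count table needs a prey column plus run columns")
  names(counts)[1] <- "prey_id"
  counts$prey_id <- as.character(counts$prey_id)
  validate_count_table(counts, design)
}

#' Validate a spectral-count table against a design
#'
#' @param counts Data frame: `prey_id` column plus one column per run.
#' @param design A [bioid_design()].
#' @return The validated tibble (columns reordered to design order), with
#'   a logical `all_zero` attribute flagging evidence-free prey rows.
#' @export
validate_count_table <- function(counts, design) {
  counts <- as_tibble(counts)
  if (!"prey_id" %in% names(counts)) {
    names(counts)[1] <- "prey_id"
  }
  run_cols <- setdiff(names(counts), "prey_id")
  missing_runs <- setdiff(design$run_id, run_cols)
  if (length(missing_runs)) {
    abort(paste0("count table is missing run column(s): ",
                 paste(missing_runs, collapse = ", ")))
  }
  extra <- setdiff(run_cols, design$run_id)
  if (length(extra)) {
    abort(paste0("count table has column(s) not in the design: ",
                 paste(extra, collapse = ", ")))
  }
  dup <- unique(counts$prey_id[duplicated(counts$prey_id)])
  if (length(dup)) {
    abort(paste0("duplicate prey id(s): ", paste(dup, collapse = ", ")))
  }
  counts <- counts[c("prey_id", design$run_id)]
  m <- as.matrix(counts[design$run_id])
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    first <- bad[1, ]
    abort(sprintf(
      "spectral counts must be non-negative integers; offending cell: prey '%s', run '%s' (value %s)",
      counts$prey_id[first[1]], design$run_id[first[2]],
      format(m[first[1], first[2]])))
  }
  counts[design$run_id] <- lapply(counts[design$run_id], as.integer)
  attr(counts, "all_zero") <- setNames(rowSums(m) == 0, counts$prey_id)
  counts
}

#' Write a spectral-count table
#'
#' @param counts Count tibble (`prey_id` plus run columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' Preys with zero counts in every run
#'
#' @param counts Count tibble.
#' @return Character vector of prey ids whose counts are all zero.
#' @export
all_zero_preys <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "prey_id")])
  counts$prey_id[rowSums(m != 0) == 0]
}

# prey x run numeric matrix view of a count tibble, rows named by prey
spc_matrix <- function(counts, run_ids = NULL) {
  run_ids <- run_ids %||% setdiff(names(counts), "prey_id")
  m <- as.matrix(counts[run_ids])
  rownames(m) <- counts$prey_id
  storage.mode(m) <- "double"
  m
}

bait_row_counts <- function(counts, design) {
  bait <- bait_prey_id(design)
  if (!bait %in% counts$prey_id) {
    abort(sprintf("bait prey row '%s' not found in the count table", bait))
  }
  unlist(counts[counts$prey_id == bait, design$run_id])
}
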