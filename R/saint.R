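#' Export the SAINT input file triplet
#'
#' Writes the three tab-separated files consumed by the SAINT /
#' SAINTexpress family of scoring tools: the interaction file (IP run id,
#' bait id, prey id, spectral count; zero-count pairs omitted), the bait
#' file (IP run id, bait id, `T` for bait purifications and `C` for
#' controls) and the prey file (prey id, protein-length placeholder, gene
#' name). Protein lengths are not part of the count-table contract, so a
#' constant placeholder length is written and the prey id doubles as the
#' gene name.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param design A [bioid_design()].
#' @param dir Output directory (created if missing).
#' @param length_placeholder Integer written in the prey-length column.
#' @return Named character vector of the three file paths, invisibly.
#' @export
export_saint_triplet <- function(counts, design, dir,
                                 length_placeholder = 100L) {
  counts <- validate_count_table(counts, design)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  long <- tidyr::pivot_longer(counts, -"prey_id", names_to = "run_id",
                              values_to = "count")
  long <- dplyr::left_join(long, as_tibble(design)[c("run_id", "bait_id")],
                           by = "run_id")
  inter <- long[long$count > 0, c("run_id", "bait_id", "prey_id", "count")]

  baits <- tibble(
    run_id = design$run_id,
    bait_id = design$bait_id,
    flag = ifelse(design$condition == "control", "C", "T")
  )
  preys <- tibble(
    prey_id = counts$prey_id,
    length = as.integer(length_placeholder),
    gene = counts$prey_id
  )

  paths <- c(
    interaction = file.path(dir, "interaction.txt"),
    bait = file.path(dir, "bait.txt"),
    prey = file.path(dir, "prey.txt")
  )
  readr::write_tsv(inter, paths[["interaction"]], col_names = FALSE)
  readr::write_tsv(baits, paths[["bait"]], col_names = FALSE)
  readr::write_tsv(preys, paths[["prey"]], col_names = FALSE)
  invisible(paths)
}
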