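# Corpus geometry mining: entry filters and pooled per-measurement
# statistics, the methodology behind small-molecule-derived restraints.

#' Describe a small-molecule search mode
#'
#' `"S"` restricts the coordination partner to sulfur (the strict search);
#' `"X"` allows any partner element. The R-factor cutoff is inclusive.
#'
#' @param label `"S"` or `"X"`.
#' @param r_cutoff R-factor cutoff (fraction).
#' @return A list of class `sf4_search_mode`.
#' @export
search_mode <- function(label = c("S", "X"), r_cutoff = 0.05) {
  label <- match.arg(label)
  stopifnot(r_cutoff > 0)
  structure(list(label = label, r_cutoff = r_cutoff),
            class = "sf4_search_mode")
}

#' Filter small-molecule entries by R factor
#'
#' Keeps entries with `r_factor <= r_cutoff` (inclusive, so an entry at
#' exactly the cutoff is kept). When the metadata carries the
#' `has_3d` / `no_errors` booleans they must be `TRUE`. The S/X partner
#' distinction is applied downstream at the instance level, in
#' [aggregate_geometry()].
#'
#' @param entries Metadata tibble with at least `entry_id` and `r_factor`.
#' @param mode An [search_mode()].
#' @return The kept subset.
#' @export
filter_small_molecule <- function(entries, mode = search_mode()) {
  stopifnot(inherits(mode, "sf4_search_mode"))
  keep <- !is.na(entries$r_factor) & entries$r_factor <= mode$r_cutoff
  if ("has_3d" %in% names(entries)) {
    keep <- keep & !is.na(entries$has_3d) & entries$has_3d
  }
  if ("no_errors" %in% names(entries)) {
    keep <- keep & !is.na(entries$no_errors) & entries$no_errors
  }
  entries[keep, , drop = FALSE]
}

#' Filter entries for refinement suitability
#'
#' The deposited-structure filters used before re-refinement: resolution
#' at 3.55 A or better, structure factors deposited and not twinned,
#' completeness >= 90%, starting R_work < 30% and R_free < 35%, and
#' R_free - R_work >= 1.5% (guarding against entries whose deposited
#' R_free test set is wrong). Entries missing a required field are
#' dropped; the reasons are attached as the `"dropped"` attribute.
#'
#' @param entries Metadata tibble with columns `entry_id`, `resolution`,
#'   `r_work`, `r_free`, `completeness`, `twinned`,
#'   `has_structure_factors`.
#' @return The kept subset, with a `dropped` attribute (tibble of
#'   `entry_id`, `reason`).
#' @export
filter_refinement_entries <- function(entries) {
  reason <- rep(NA_character_, nrow(entries))
  need <- c("resolution", "r_work", "r_free", "completeness", "twinned",
            "has_structure_factors")
  for (col in need) {
    if (!col %in% names(entries)) {
      stop("metadata is missing required column '", col, "'", call. = FALSE)
    }
    miss <- is.na(reason) & is.na(entries[[col]])
    reason[miss] <- paste0("missing ", col)
  }
  rule <- function(ok, why) {
    fail <- is.na(reason) & !ok
    reason[fail] <<- why
  }
  rule(entries$resolution <= 3.55, "resolution worse than 3.55 A")
  rule(entries$has_structure_factors, "no deposited structure factors")
  rule(!entries$twinned, "twinned data")
  rule(entries$completeness >= 0.90, "completeness below 90%")
  rule(entries$r_work < 0.30, "R_work >= 30%")
  rule(entries$r_free < 0.35, "R_free >= 35%")
  rule(entries$r_free - entries$r_work >= 0.015,
       "R_free - R_work below 1.5%")
  kept <- entries[is.na(reason), , drop = FALSE]
  attr(kept, "dropped") <- tibble::tibble(
    entry_id = entries$entry_id[!is.na(reason)],
    reason = reason[!is.na(reason)])
  kept
}

#' Filter for very-high-resolution entries
#'
#' Entries solved strictly better than 1 A with deposited structure
#' factors (and, when the column is present, a complete cluster).
#'
#' @param entries Metadata tibble.
#' @return The kept subset.
#' @export
filter_high_res <- function(entries) {
  keep <- !is.na(entries$resolution) & entries$resolution < 1.0 &
    !is.na(entries$has_structure_factors) & entries$has_structure_factors
  if ("cluster_complete" %in% names(entries)) {
    keep <- keep & !is.na(entries$cluster_complete) &
      entries$cluster_complete
  }
  entries[keep, , drop = FALSE]
}

#' Pool geometry statistics over cluster profiles
#'
#' Per parameter class, the mean and sample standard deviation
#' (n - 1 denominator) over every individual measurement of every
#' profile: each of a cluster's 12 bonds and 24 angles contributes one
#' observation, so the pooling is per measurement, not per entry. In the
#' `"S"` search mode, link measurements (Fe-S_AA, S-Fe-S_AA) are
#' restricted to cysteine-sulfur partners.
#'
#' @param profiles A list of profile tibbles from [cluster_profile()], or
#'   one already-bound measurement tibble.
#' @param mode Optional [search_mode()] controlling link-partner
#'   filtering.
#' @return A tibble of class `sf4_stats` with columns `class`, `mean`,
#'   `sd`, `n`.
#' @export
aggregate_geometry <- function(profiles, mode = NULL) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (!length(profiles)) {
    stop("empty corpus: no profiles to aggregate", call. = FALSE)
  }
  all_rows <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  if (!nrow(all_rows)) {
    stop("empty corpus: no measurements to aggregate", call. = FALSE)
  }
  if (!is.null(mode) && mode$label == "S" &&
      "partner_residue" %in% names(all_rows)) {
    is_link <- all_rows$class %in% c("Fe-S_AA", "S-Fe-S_AA")
    all_rows <- all_rows[!is_link | all_rows$partner_residue %in% "CYS", ]
  }
  out <- all_rows |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  structure(out, class = c("sf4_stats", class(out)))
}

#' Load a corpus directory into a tibble
#'
#' @param dir Directory of coordinate files.
#' @param metadata Metadata tibble (or path to its CSV) with `entry_id`
#'   and `file` columns; `file` paths are taken relative to `dir`.
#' @return The metadata tibble with a `model` list-column of atom tables.
#' @export
load_corpus <- function(dir, metadata = file.path(dir, "metadata.csv")) {
  if (is.character(metadata)) {
    metadata <- readr::read_csv(metadata, show_col_types = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  metadata$model <- lapply(file.path(dir, metadata$file), read_structure)
  metadata
}

#' Mine pooled geometry statistics from a corpus
#'
#' Convenience pipeline: load the corpus, measure every complete cluster
#' (with its cysteine links), and pool the statistics.
#'
#' @param corpus A corpus tibble from [load_corpus()].
#' @param mode An [search_mode()].
#' @param cutoff Link detection cutoff (Angstrom).
#' @return An `sf4_stats` tibble.
#' @export
mine_corpus <- function(corpus, mode = search_mode(), cutoff = 3.0) {
  profiles <- list()
  for (k in seq_len(nrow(corpus))) {
    model <- corpus$model[[k]]
    for (cl in find_clusters(model)) {
      links <- detect_links(cl, model, cutoff = cutoff)
      profiles[[length(profiles) + 1L]] <-
        cluster_profile(cl, links = if (nrow(links)) links)
    }
  }
  aggregate_geometry(profiles, mode = mode)
}

#' @export
print.sf4_stats <- function(x, ...) {
  cat("Pooled SF4 geometry statistics\n")
  NextMethod()
}
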