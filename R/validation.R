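# Restraint-RMSD validation and cluster classification.

#' Bond and angle RMSD of a profile against a restraint set
#'
#' Root-mean-square of (measured - target) over the 12 internal bonds and
#' the 24 internal angles, unweighted by default (raw Angstrom / degree
#' deviations); `sigma_weighted = TRUE` divides each deviation by its
#' restraint sigma instead. When a link definition is supplied and the
#' profile carries link measurements, the Fe-S_AA bonds and S-Fe-S_AA
#' angles join their respective pools.
#'
#' @param profile A measurement tibble from [cluster_profile()].
#' @param set An `sf4_restraints` object.
#' @param link Optional `sf4_link` definition.
#' @param sigma_weighted Normalize deviations by sigma.
#' @return A one-row tibble: `bond_rmsd`, `angle_rmsd`, `n_bonds`,
#'   `n_angles`.
#' @export
rmsd_to_restraints <- function(profile, set, link = NULL,
                               sigma_weighted = FALSE) {
  stopifnot(inherits(set, "sf4_restraints"))
  n_int_bonds <- sum(profile$class == "S-Fe")
  n_fesfe <- sum(profile$class == "Fe-S-Fe")
  n_sfes <- sum(profile$class == "S-Fe-S")
  if (n_int_bonds != 12L || n_fesfe != 12L || n_sfes != 12L) {
    stop("inconsistent set: profile has ", n_int_bonds, "/", n_fesfe, "/",
         n_sfes, " internal measurements, expected 12/12/12", call. = FALSE)
  }
  targets <- c(
    "S-Fe" = set$bonds$value[1],
    "Fe-S-Fe" = set$angles$value[set$angles$class == "Fe-S-Fe"][1],
    "S-Fe-S" = set$angles$value[set$angles$class == "S-Fe-S"][1])
  sigmas <- c(
    "S-Fe" = set$bonds$sigma[1],
    "Fe-S-Fe" = set$angles$sigma[set$angles$class == "Fe-S-Fe"][1],
    "S-Fe-S" = set$angles$sigma[set$angles$class == "S-Fe-S"][1])
  keep <- profile$class %in% names(targets)
  if (!is.null(link)) {
    stopifnot(inherits(link, "sf4_link"))
    targets <- c(targets, "Fe-S_AA" = link$bond$value,
                 "S-Fe-S_AA" = link$angle$value)
    sigmas <- c(sigmas, "Fe-S_AA" = link$bond$sigma,
                "S-Fe-S_AA" = link$angle$sigma)
    keep <- profile$class %in% names(targets)
  }
  prof <- profile[keep, ]
  dev <- prof$value - targets[prof$class]
  if (sigma_weighted) dev <- dev / sigmas[prof$class]
  is_bond <- prof$class %in% c("S-Fe", "Fe-S_AA")
  tibble::tibble(
    bond_rmsd = sqrt(mean(dev[is_bond]^2)),
    angle_rmsd = sqrt(mean(dev[!is_bond]^2)),
    n_bonds = sum(is_bond),
    n_angles = sum(!is_bond))
}

#' Classify an observed cluster
#'
#' `"misnamed"` when the optimal chirality-preserving relabeling is not
#' the identity (per [is_misnamed()]); otherwise `"cubic"` or
#' `"rhomboid"` by whichever restraint set gives the smaller internal
#' angle RMSD. Angles, not bonds, drive the call because the angle
#' targets (90 vs 73.66/104.18 degrees) separate the two geometries far
#' more than the 0.154 A bond difference.
#'
#' @param cluster An 8-atom cluster tibble.
#' @param rhomboid,cubic Restraint sets to compare against.
#' @param template Reference template for the naming check.
#' @return `"rhomboid"`, `"cubic"` or `"misnamed"`.
#' @export
classify_cluster <- function(cluster, rhomboid = rhomboid_restraints(),
                             cubic = cubic_restraints(),
                             template = build_rhomboid()) {
  cluster <- validate_cluster(cluster)
  mapping <- best_mapping(cluster, template)
  if (is_misnamed(mapping)) return("misnamed")
  prof <- cluster_profile(cluster)
  r_rh <- rmsd_to_restraints(prof, rhomboid)
  r_cu <- rmsd_to_restraints(prof, cubic)
  if (r_cu$angle_rmsd < r_rh$angle_rmsd) "cubic" else "rhomboid"
}

#' Per-resolution-bin RMSD report over a corpus
#'
#' Validates every model of a corpus against one restraint set and
#' aggregates mean cluster bond/angle RMSD per resolution bin.
#'
#' @param corpus A tibble with columns `entry_id`, `resolution`, and a
#'   list-column `model` of atom tibbles (see [load_corpus()]).
#' @param set An `sf4_restraints` object.
#' @param bin_width Resolution bin width in Angstrom.
#' @return A tibble of class `sf4_corpus_report`: one row per bin with
#'   `resolution_mid`, `n`, `bond_rmsd`, `angle_rmsd`.
#' @export
corpus_report <- function(corpus, set, bin_width = 0.25) {
  stopifnot(is.data.frame(corpus), inherits(set, "sf4_restraints"))
  empty <- tibble::tibble(resolution_mid = numeric(), n = integer(),
                          bond_rmsd = numeric(), angle_rmsd = numeric())
  if (!nrow(corpus)) {
    return(structure(empty, class = c("sf4_corpus_report", class(empty))))
  }
  per_model <- purrr::map_dfr(seq_len(nrow(corpus)), function(k) {
    res <- corpus$resolution[k]
    if (is.na(res)) {
      warning("entry ", corpus$entry_id[k],
              " has no resolution; skipped", call. = FALSE)
      return(NULL)
    }
    clusters <- find_clusters(corpus$model[[k]])
    purrr::map_dfr(clusters, function(cl) {
      dplyr::mutate(rmsd_to_restraints(cluster_profile(cl), set),
                    resolution = res)
    })
  })
  if (!nrow(per_model)) {
    return(structure(empty, class = c("sf4_corpus_report", class(empty))))
  }
  lo <- floor(min(per_model$resolution) / bin_width) * bin_width
  hi <- ceiling(max(per_model$resolution) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  out <- per_model |>
    dplyr::mutate(bin = cut(.data$resolution, breaks = breaks,
                            include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     bond_rmsd = mean(.data$bond_rmsd),
                     angle_rmsd = mean(.data$angle_rmsd),
                     .groups = "drop") |>
    dplyr::mutate(resolution_mid = breaks[as.integer(.data$bin)] +
                    bin_width / 2) |>
    dplyr::select("resolution_mid", "n", "bond_rmsd", "angle_rmsd")
  structure(out, class = c("sf4_corpus_report", class(out)),
            label = set$label, bin_width = bin_width)
}

#' Plot a corpus RMSD report
#'
#' Cluster bond and angle RMSD against resolution, with per-bin counts.
#'
#' @param object An `sf4_corpus_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sf4_corpus_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("bond_rmsd", "angle_rmsd"),
                              names_to = "metric", values_to = "rmsd")
  long$metric <- factor(long$metric, c("bond_rmsd", "angle_rmsd"),
                        c("bond r.m.s.d. (Å)",
                          "angle r.m.s.d. (°)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resolution_mid,
                                     y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "resolution (Å)", y = NULL, size = "clusters",
                  title = paste0("Cluster geometry vs ",
                                 attr(object, "label") %||% "restraint",
                                 " targets")) +
    ggplot2::theme_minimal()
}

#' Validate one model end to end
#'
#' Finds clusters, detects cysteine links, and reports RMSD and
#' classification per cluster.
#'
#' @param model An atom tibble.
#' @param set Restraint set to validate against.
#' @param link Optional link definition for the coordination terms.
#' @param cutoff Link detection cutoff (Angstrom).
#' @return A tibble with one row per cluster: `source_id`, `n_links`,
#'   RMSD columns and `classification`.
#' @export
validate_model <- function(model, set = rhomboid_restraints(),
                           link = link_definition(), cutoff = 3.0) {
  clusters <- find_clusters(model)
  purrr::map_dfr(clusters, function(cl) {
    links <- detect_links(cl, model, cutoff = cutoff)
    prof <- cluster_profile(cl, links = if (nrow(links)) links)
    rmsd <- rmsd_to_restraints(prof, set,
                               link = if (nrow(links)) link)
    dplyr::mutate(rmsd,
                  source_id = attr(cl, "source_id"),
                  n_links = nrow(links),
                  classification = classify_cluster(cl),
                  .before = 1)
  })
}
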