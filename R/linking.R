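# Detection of SF4 clusters and their coordinating cysteine sulfurs, and
# emission of the corresponding link restraints.

#' Find SF4 clusters in a model
#'
#' One cluster per SF4 residue holding all eight atoms (4 Fe + 4 S);
#' incomplete residues are reported with a warning and omitted.
#'
#' @param model An atom tibble from [read_structure()].
#' @return A list of 8-row cluster tibbles, each carrying a `source_id`
#'   attribute (`"<chain>_<residue_number>"`).
#' @export
find_clusters <- function(model) {
  sf4 <- model[model$residue_name == "SF4", ]
  if (!nrow(sf4)) return(list())
  keys <- unique(sf4[, c("chain_id", "residue_number")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    cl <- sf4[sf4$chain_id == keys$chain_id[k] &
                sf4$residue_number == keys$residue_number[k], ]
    sid <- paste0(keys$chain_id[k], "_", keys$residue_number[k])
    if (sum(cl$element == "Fe") != 4L || sum(cl$element == "S") != 4L) {
      warning("SF4 residue ", sid, " is incomplete (",
              nrow(cl), " atoms); skipped", call. = FALSE)
      next
    }
    cl <- validate_cluster(cl)
    attr(cl, "source_id") <- sid
    out[[length(out) + 1L]] <- cl
  }
  out
}

#' Detect iron-to-cysteine coordination links
#'
#' For each iron of the cluster, the nearest coordinating sulfur within
#' `cutoff` (cysteine SG by default; any non-cluster sulfur with
#' `any_sulfur = TRUE`). Assignment is greedy nearest-first, so each iron
#' gets at most one partner and each partner at most one iron; ties at
#' machine precision fall back to chain/residue order with a warning.
#'
#' @param cluster An 8-atom cluster tibble.
#' @param model The full atom tibble the cluster came from.
#' @param cutoff Maximum Fe-S_AA distance (Angstrom). The default 3.0 A
#'   sits far above the observed 2.268 A coordination bond yet below
#'   nonbonded sulfur contacts.
#' @param any_sulfur Extend partners beyond CYS SG to any sulfur atom
#'   outside the cluster (e.g. MET SD); the same bond target is applied,
#'   as an approximation, with a warning downstream.
#' @return A tibble with one row per link: `fe_atom`, partner identity,
#'   coordinates of both atoms and `distance`.
#' @export
detect_links <- function(cluster, model, cutoff = 3.0, any_sulfur = FALSE) {
  cluster <- validate_cluster(cluster)
  fe <- cluster[cluster$element == "Fe", ]
  cand <- model[model$element == "S", ]
  # exclude the cluster's own residue
  cand <- cand[!(cand$residue_name == "SF4" &
                   cand$chain_id == cluster$chain_id[1] &
                   cand$residue_number == cluster$residue_number[1]), ]
  cand <- cand[cand$residue_name != "SF4" | any_sulfur, ]
  if (!any_sulfur) {
    cand <- cand[cand$residue_name == "CYS" & cand$atom_name == "SG", ]
  }
  empty <- tibble::tibble(
    fe_atom = character(), partner_residue = character(),
    partner_chain = character(), partner_number = integer(),
    partner_atom = character(), distance = numeric(),
    fe_x = numeric(), fe_y = numeric(), fe_z = numeric(),
    sg_x = numeric(), sg_y = numeric(), sg_z = numeric())
  if (!nrow(cand)) return(empty)

  fexyz <- .atom_xyz(fe)
  cxyz <- .atom_xyz(cand)
  pairs <- expand.grid(i = seq_len(nrow(fe)), j = seq_len(nrow(cand)))
  pairs$distance <- sqrt(rowSums((fexyz[pairs$i, , drop = FALSE] -
                                    cxyz[pairs$j, , drop = FALSE])^2))
  pairs <- pairs[pairs$distance <= cutoff, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  # ties only matter between two candidates competing for the same iron
  # (or one sulfur claimed by two irons at the same distance)
  tied <- any(tapply(signif(pairs$distance, 12), pairs$i, anyDuplicated) > 0) ||
    any(tapply(signif(pairs$distance, 12), pairs$j, anyDuplicated) > 0)
  if (isTRUE(tied)) {
    warning("equidistant link candidates; tie resolved by chain/residue ",
            "order", call. = FALSE)
  }
  pairs <- pairs[order(pairs$distance, cand$chain_id[pairs$j],
                       cand$residue_number[pairs$j]), , drop = FALSE]
  used_fe <- logical(nrow(fe))
  used_sg <- logical(nrow(cand))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]
    j <- pairs$j[r]
    if (used_fe[i] || used_sg[j]) next
    used_fe[i] <- TRUE
    used_sg[j] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fe_atom = fe$atom_name[i],
      partner_residue = cand$residue_name[j],
      partner_chain = cand$chain_id[j],
      partner_number = cand$residue_number[j],
      partner_atom = cand$atom_name[j],
      distance = pairs$distance[r],
      fe_x = fexyz[i, 1], fe_y = fexyz[i, 2], fe_z = fexyz[i, 3],
      sg_x = cxyz[j, 1], sg_y = cxyz[j, 2], sg_z = cxyz[j, 3])
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$fe_atom), ]
}

#' Emit link restraint records for detected links
#'
#' Per link: one bond restraint (Fe to the coordinating sulfur) and three
#' angle restraints from the iron's internal sulfurs through the iron to
#' the partner, with the targets of the supplied link definition.
#'
#' @param links Link tibble from [detect_links()] (nonempty).
#' @param definition An [link_definition()].
#' @param cluster The cluster the links belong to (for the internal-sulfur
#'   adjacency).
#' @return A tibble of restraint records (`type`, atoms, `value`, `sigma`).
#' @export
emit_link_restraints <- function(links, definition = link_definition(),
                                 cluster) {
  stopifnot(inherits(definition, "sf4_link"))
  if (is.null(links) || nrow(links) == 0) {
    stop("no links to emit restraints for", call. = FALSE)
  }
  cluster <- validate_cluster(cluster)
  g <- .cluster_adjacency(cluster)
  if (any(links$partner_residue != "CYS")) {
    warning("non-CYS sulfur partner(s): applying the CYS link targets as ",
            "an approximation", call. = FALSE)
  }
  rows <- list()
  for (k in seq_len(nrow(links))) {
    li <- links[k, ]
    i <- match(li$fe_atom, g$fe$atom_name)
    if (is.na(i)) {
      stop("orphan link: iron '", li$fe_atom,
           "' is not part of the supplied cluster", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = "bond", atom_1 = li$fe_atom, atom_2 = li$partner_atom,
      atom_3 = NA_character_,
      partner = paste0(li$partner_residue, " ", li$partner_chain,
                       li$partner_number),
      value = definition$bond$value, sigma = definition$bond$sigma)
    for (j in which(g$adj[i, ])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "angle", atom_1 = g$s$atom_name[j], atom_2 = li$fe_atom,
        atom_3 = li$partner_atom,
        partner = paste0(li$partner_residue, " ", li$partner_chain,
                         li$partner_number),
        value = definition$angle$value, sigma = definition$angle$sigma)
    }
  }
  dplyr::bind_rows(rows)
}
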