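# Canonicalization of SF4 atom names.
#
# All four irons (and all four sulfurs) are chemically identical, so the
# deposited atom naming is arbitrary up to an automorphism of the cubane
# bond graph. The automorphisms that preserve element are exactly the
# pairs (pi, pi) acting identically on the Fe and S indices (S_i is
# antipodal to FE_i, and the antipodal matching must be preserved): 24 in
# total, of which the 12 even permutations are realizable by proper
# rotations of the cluster. Renaming searches those 12 with a closed-form
# least-squares superposition per candidate.

# All permutations of 1..4 in lexicographic order.
.perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b))) {
    out[[length(out) + 1L]] <- c(a, b, c, setdiff(1:4, c(a, b, c)))
  }
  out
}

# Kabsch superposition of P onto Q (both n x 3). Proper rotation
# (det = +1) unless allow_reflection; returns rotation, translation, rmsd.
.kabsch <- function(P, Q, allow_reflection = FALSE) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc)
  Q0 <- sweep(Q, 2, qc)
  s <- svd(t(P0) %*% Q0)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, if (allow_reflection) 1 else d))
  R <- s$v %*% D %*% t(s$u)
  fit <- P0 %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fit - Q0)^2))),
       proper = det(R) > 0)
}

.relabeling_from_perm <- function(p) {
  stats::setNames(
    c(canonical_fe_names()[p], canonical_s_names()[p]),
    canonical_atom_names())
}

#' Enumerate the topology-preserving relabelings of SF4
#'
#' Scans all 576 element-preserving bijections of the eight canonical
#' names (4! iron permutations times 4! sulfur permutations) and keeps
#' those preserving cubane adjacency: 24 in total. With
#' `chirality_preserving = TRUE` (the default) only the 12 relabelings
#' realizable by a proper rotation of the reference template are
#' returned, determined by superposing the template onto its relabeled
#' self and requiring a proper-rotation fit with zero residual.
#'
#' @param chirality_preserving Restrict to proper-rotation relabelings.
#' @return A list of named character vectors (observed name -> canonical
#'   name); the identity is always first.
#' @export
enumerate_relabelings <- function(chirality_preserving = TRUE) {
  perms <- .perms4()
  fe <- canonical_fe_names()
  s <- canonical_s_names()
  keep <- list()
  for (pf in perms) {
    for (ps in perms) {
      # adjacency FE_i ~ S_j iff i != j must be preserved:
      # (i != j) <=> (pf[i] != ps[j]) for all i, j
      ok <- TRUE
      for (i in 1:4) {
        for (j in 1:4) {
          if ((i != j) != (pf[i] != ps[j])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        keep[[length(keep) + 1L]] <- stats::setNames(
          c(fe[pf], s[ps]), canonical_atom_names())
      }
    }
  }
  if (chirality_preserving) {
    tmpl <- build_rhomboid()
    txyz <- .atom_xyz(tmpl)
    keep <- Filter(function(m) {
      perm <- match(m[canonical_atom_names()], canonical_atom_names())
      fit <- .kabsch(txyz, txyz[order(perm), , drop = FALSE])
      fit$proper && fit$rmsd < 1e-6
    }, keep)
  }
  ids <- vapply(keep, function(m) paste(m, collapse = " "), "")
  keep[order(ids != paste(canonical_atom_names(), collapse = " "), ids)]
}

# Is relabeling m realizable by a proper rotation of the reference
# template (i.e. is it one of the chirality-preserving 12)?
.relabeling_proper <- function(m, txyz) {
  perm <- match(m[canonical_atom_names()], canonical_atom_names())
  fit <- .kabsch(txyz, txyz[order(perm), , drop = FALSE])
  fit$proper && fit$rmsd < 1e-6
}

#' Find the best canonical naming of an observed cluster
#'
#' Superposes the ideal template onto the cluster under candidate
#' relabelings using a proper-rotation least-squares fit (reflections are
#' never applied to coordinates), and returns the relabeling with minimal
#' RMSD; ties are broken by the lexicographically smallest relabeling.
#'
#' The ideal cluster is exactly invariant under the 12
#' chirality-preserving relabelings, so those always tie with the
#' identity: any of them is an equally correct naming. The naming errors
#' that matter are the 12 chirality-breaking relabelings, which cannot be
#' reached by rotating the cluster; the default search therefore spans
#' all 24 adjacency-preserving relabelings, and the winner is either the
#' identity (naming consistent with the restraint handedness) or a
#' chirality-breaking corrective relabeling (`rotation_proper = FALSE`,
#' the deposited names imply inverted handedness). Restricting the search
#' with `relabelings = "proper"` measures how well the cluster fits
#' without changing handedness: for a mirror-imaged cluster that
#' proper-restricted RMSD is large (> 0.5 A for ideal geometry).
#'
#' @param cluster A complete 8-atom cluster tibble with canonical atom
#'   names (in any assignment).
#' @param template Reference `sf4_template` (defaults to the rhomboid
#'   ideal template).
#' @param relabelings `"all"` (24 candidates, default) or `"proper"`
#'   (the chirality-preserving 12).
#' @param mirror_threshold Proper-restricted RMSD (Angstrom) above which
#'   inverted chirality is flagged.
#' @return An object of class `sf4_mapping`: list with `relabeling`
#'   (named character vector observed -> canonical), `rmsd`,
#'   `rmsd_identity` (= the best proper-restricted RMSD, since the
#'   identity ties it exactly), `identity` flag, `rotation_proper`
#'   (winner is chirality-preserving), `chirality_flag`, and the
#'   cluster's `chain_id` / `residue_number`.
#' @export
best_mapping <- function(cluster, template = build_rhomboid(),
                         relabelings = c("all", "proper"),
                         mirror_threshold = 0.5) {
  relabelings <- match.arg(relabelings)
  cluster <- validate_cluster(cluster)
  if (!setequal(cluster$atom_name, canonical_atom_names())) {
    stop("cluster atom names are not the canonical SF4 set", call. = FALSE)
  }
  txyz <- .atom_xyz(template)
  cxyz <- .atom_xyz(cluster)  # ordered FE1..FE4, S1..S4 by observed name
  candidates <- enumerate_relabelings(
    chirality_preserving = relabelings == "proper")
  best <- NULL
  rmsd_identity <- NA_real_
  for (m in candidates) {
    # observed atom named o is asserted to be canonical m[o]: template row
    # for m[o] must superpose onto the observed row for o.
    perm <- match(m[canonical_atom_names()], canonical_atom_names())
    fit <- .kabsch(txyz[perm, , drop = FALSE], cxyz)
    id <- paste(m, collapse = " ")
    is_identity <- identical(unname(m), names(m))
    if (is_identity) rmsd_identity <- fit$rmsd
    cand <- list(relabeling = m, rmsd = fit$rmsd, id = id)
    if (is.null(best) || cand$rmsd < best$rmsd - 1e-12 ||
        (abs(cand$rmsd - best$rmsd) <= 1e-12 && cand$id < best$id)) {
      best <- cand
    }
  }
  proper <- .relabeling_proper(best$relabeling, txyz)
  structure(list(
    relabeling = best$relabeling,
    rmsd = best$rmsd,
    rmsd_identity = rmsd_identity,
    identity = identical(unname(best$relabeling), names(best$relabeling)),
    rotation_proper = proper,
    chirality_flag = !proper || rmsd_identity > mirror_threshold,
    chain_id = cluster$chain_id[1],
    residue_number = cluster$residue_number[1]),
    class = "sf4_mapping")
}

#' Does a mapping flag incorrect atom naming?
#'
#' A model counts as misnamed when the optimal relabeling is not the
#' identity and improves on the identity fit by more than
#' `improvement` Angstrom of RMSD.
#'
#' @param mapping An `sf4_mapping` from [best_mapping()].
#' @param improvement Required RMSD improvement (Angstrom).
#' @return `TRUE` or `FALSE`.
#' @export
is_misnamed <- function(mapping, improvement = 0.1) {
  !mapping$identity && (mapping$rmsd_identity - mapping$rmsd) > improvement
}

#' Apply an atom-name mapping to a model
#'
#' Replaces the atom names of the mapped cluster residue according to the
#' relabeling; coordinates and every other field are untouched.
#'
#' @param model An atom tibble containing the mapped cluster.
#' @param mapping An `sf4_mapping` from [best_mapping()].
#' @return The renamed model tibble.
#' @export
rename_atoms <- function(model, mapping) {
  stopifnot(inherits(mapping, "sf4_mapping"))
  idx <- which(model$chain_id == mapping$chain_id &
                 model$residue_number == mapping$residue_number &
                 model$residue_name == "SF4")
  if (!length(idx)) {
    stop("model has no SF4 residue at chain ", mapping$chain_id,
         " number ", mapping$residue_number, call. = FALSE)
  }
  old <- model$atom_name[idx]
  unknown <- setdiff(old, names(mapping$relabeling))
  if (length(unknown)) {
    stop("rename conflict: atoms ", paste(unknown, collapse = ", "),
         " in the target residue are not covered by the mapping",
         call. = FALSE)
  }
  new <- unname(mapping$relabeling[old])
  if (anyDuplicated(new)) {
    stop("rename conflict: mapping produces duplicate atom names",
         call. = FALSE)
  }
  model$atom_name[idx] <- new
  model
}

#' @export
print.sf4_mapping <- function(x, ...) {
  cat("SF4 atom-name mapping (chain ", x$chain_id, ", residue ",
      x$residue_number, ")\n", sep = "")
  cat("  identity:", x$identity, " rmsd:", signif(x$rmsd, 4), "A\n")
  if (x$chirality_flag) cat("  WARNING: possible inverted chirality\n")
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.sf4_mapping <- function(x, ...) {
  tibble::tibble(observed = names(x$relabeling),
                 canonical = unname(x$relabeling))
}

#' @exportS3Method broom::glance
glance.sf4_mapping <- function(x, ...) {
  tibble::tibble(chain_id = x$chain_id,
                 residue_number = x$residue_number,
                 identity = x$identity,
                 rmsd = x$rmsd,
                 rmsd_identity = x$rmsd_identity,
                 rotation_proper = x$rotation_proper,
                 chirality_flag = x$chirality_flag,
                 misnamed = is_misnamed(x))
}
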