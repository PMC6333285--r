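# Restraint dictionaries for the SF4 component and the SF4-CYS link.
#
# A component set holds 12 bond restraints (every Fe_i - S_j pair with
# i != j), 24 angle restraints (12 Fe-S-Fe at the sulfur vertices, 12
# S-Fe-S at the iron vertices) and 4 chiral restraints (one per iron over
# its three sulfurs in ascending name order). Values come from pooled
# small-molecule statistics; sigmas are the pooled standard deviations and
# act as refinement weights.

.bond_pairs <- function() {
  fe <- canonical_fe_names()
  s <- canonical_s_names()
  out <- expand.grid(i = 1:4, j = 1:4)
  out <- out[out$i != out$j, ]
  out <- out[order(out$i, out$j), ]
  tibble::tibble(atom_1 = fe[out$i], atom_2 = s[out$j])
}

.angle_triples <- function() {
  fe <- canonical_fe_names()
  s <- canonical_s_names()
  rows <- list()
  # Fe-S-Fe at each sulfur vertex j: irons i != j
  for (j in 1:4) {
    nb <- setdiff(1:4, j)
    for (pr in utils::combn(nb, 2, simplify = FALSE)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = "Fe-S-Fe", atom_1 = fe[pr[1]], atom_2 = s[j],
        atom_3 = fe[pr[2]])
    }
  }
  # S-Fe-S at each iron vertex i: sulfurs j != i
  for (i in 1:4) {
    nb <- setdiff(1:4, i)
    for (pr in utils::combn(nb, 2, simplify = FALSE)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = "S-Fe-S", atom_1 = s[pr[1]], atom_2 = fe[i],
        atom_3 = s[pr[2]])
    }
  }
  dplyr::bind_rows(rows)
}

# Per-center volume signs of the reference handedness with neighbours in
# ascending name order: the tetrahedral symmetry maps FE1's ordered
# triple onto odd arrangements at FE2/FE4, so the signs alternate.
.chiral_signs <- function() c("negative", "positive", "negative", "positive")

.chiral_rows <- function(signs = .chiral_signs()) {
  fe <- canonical_fe_names()
  s <- canonical_s_names()
  purrr::map_dfr(1:4, function(i) {
    nb <- s[setdiff(1:4, i)]
    tibble::tibble(id = paste0("chir_", i), center = fe[i],
                   atom_1 = nb[1], atom_2 = nb[2], atom_3 = nb[3],
                   sign = signs[i])
  })
}

#' Construct an SF4 restraint set
#'
#' @param label `"rhomboid"` or `"cubic"`.
#' @param bond_value,bond_sigma S-Fe bond target and sigma (Angstrom).
#' @param fesfe_value,fesfe_sigma Fe-S-Fe angle target and sigma (degrees).
#' @param sfes_value,sfes_sigma S-Fe-S angle target and sigma (degrees).
#' @param chiral_signs Length-4 character vector of volume signs at
#'   FE1..FE4 (neighbours in ascending name order); the reference
#'   handedness alternates negative/positive.
#' @param comp_id Component id (always `"SF4"` here).
#' @return An object of class `sf4_restraints`: a list with `comp_id`,
#'   `label` and tibbles `bonds`, `angles`, `chirals`.
#' @export
restraint_set <- function(label, bond_value, bond_sigma,
                          fesfe_value, fesfe_sigma,
                          sfes_value, sfes_sigma,
                          chiral_signs = .chiral_signs(), comp_id = "SF4") {
  stopifnot(bond_value > 0, bond_sigma > 0,
            fesfe_value > 0, fesfe_value < 180, fesfe_sigma > 0,
            sfes_value > 0, sfes_value < 180, sfes_sigma > 0)
  bonds <- .bond_pairs()
  bonds$value <- bond_value
  bonds$sigma <- bond_sigma
  angles <- .angle_triples()
  angles$value <- ifelse(angles$class == "Fe-S-Fe", fesfe_value, sfes_value)
  angles$sigma <- ifelse(angles$class == "Fe-S-Fe", fesfe_sigma, sfes_sigma)
  structure(list(comp_id = comp_id, label = label, bonds = bonds,
                 angles = angles, chirals = .chiral_rows(chiral_signs)),
            class = "sf4_restraints")
}

#' Rhomboid SF4 restraints (small-molecule values)
#'
#' The restraint set derived from the strict S-linked small-molecule
#' search: bond 2.289 (sigma 0.024) A, Fe-S-Fe 73.66 (0.87) deg, S-Fe-S
#' 104.18 (1.24) deg, plus four sign chiral restraints that lock the
#' cluster handedness.
#'
#' @return An `sf4_restraints` object.
#' @export
rhomboid_restraints <- function() {
  restraint_set("rhomboid", 2.289, 0.024, 73.66, 0.87, 104.18, 1.24)
}

#' Cubic SF4 restraints (legacy monomer-library values)
#'
#' Bond 2.135 (sigma 0.020) A with both internal angle classes at 90
#' degrees. The angle sigmas reuse the rhomboid class sigmas (0.87 / 1.24
#' deg) so that RMSD comparisons between the two sets weight identically
#' and isolate the effect of the target values.
#'
#' @return An `sf4_restraints` object.
#' @export
cubic_restraints <- function() {
  restraint_set("cubic", 2.135, 0.020, 90, 0.87, 90, 1.24)
}

#' SF4-CYS link restraint definition
#'
#' The coordination link from a cluster iron to a cysteine SG sulfur:
#' bond 2.268 (sigma 0.017) A and S-Fe-S_AA angle 114.24 (5.75) deg
#' applied to the three internal sulfurs of the linked iron.
#'
#' @return An object of class `sf4_link`: a list with `link_id`, a
#'   one-row `bond` tibble and a one-row `angle` tibble.
#' @export
link_definition <- function() {
  structure(list(
    link_id = "SF4-CYS",
    bond = tibble::tibble(atom_1 = "FE", comp_1 = "SF4", atom_2 = "SG",
                          comp_2 = "CYS", value = 2.268, sigma = 0.017),
    angle = tibble::tibble(atom_1 = "S", comp_1 = "SF4", atom_2 = "FE",
                           comp_2 = "SF4", atom_3 = "SG", comp_3 = "CYS",
                           value = 114.24, sigma = 5.75)),
    class = "sf4_link")
}

#' Build a restraint set from mined corpus statistics
#'
#' @param stats A statistics tibble from [aggregate_geometry()] with
#'   columns `class`, `mean`, `sd`, `n`, covering the three internal
#'   parameter classes with n >= 2.
#' @return An `sf4_restraints` object; labelled `"cubic"` when both angle
#'   means lie within 5 degrees of 90, else `"rhomboid"`.
#' @export
restraints_from_stats <- function(stats) {
  need <- c("S-Fe", "Fe-S-Fe", "S-Fe-S")
  missing <- setdiff(need, stats$class)
  if (length(missing)) {
    stop("incomplete statistics: missing parameter class(es) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  row <- function(cl) stats[match(cl, stats$class), ]
  for (cl in need) {
    r <- row(cl)
    if (is.na(r$n) || r$n < 2) {
      stop("incomplete statistics: class ", cl, " has n < 2", call. = FALSE)
    }
    if (is.na(r$sd) || r$sd <= 0) {
      stop("invalid sigma: class ", cl,
           " has non-positive standard deviation", call. = FALSE)
    }
  }
  b <- row("S-Fe")
  a1 <- row("Fe-S-Fe")
  a2 <- row("S-Fe-S")
  label <- if (abs(a1$mean - 90) < 5 && abs(a2$mean - 90) < 5)
    "cubic" else "rhomboid"
  restraint_set(label, b$mean, b$sd, a1$mean, a1$sd, a2$mean, a2$sd)
}

#' @export
print.sf4_restraints <- function(x, ...) {
  cat("SF4 restraint set (", x$label, ")\n", sep = "")
  cat(sprintf("  bond    %.3f  sigma %.3f A   (%d restraints)\n",
              x$bonds$value[1], x$bonds$sigma[1], nrow(x$bonds)))
  for (cl in unique(x$angles$class)) {
    sub <- x$angles[x$angles$class == cl, ]
    cat(sprintf("  %-7s %.2f  sigma %.2f deg (%d restraints)\n",
                cl, sub$value[1], sub$sigma[1], nrow(sub)))
  }
  cat("  ", nrow(x$chirals), " chiral sign restraints\n", sep = "")
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.sf4_restraints <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$bonds, type = "bond", class = "S-Fe",
                  atom_3 = NA_character_),
    dplyr::mutate(x$angles, type = "angle"),
    tibble::tibble(type = "chiral", class = "chirality",
                   atom_1 = x$chirals$atom_1, atom_2 = x$chirals$center,
                   atom_3 = x$chirals$atom_3,
                   value = NA_real_, sigma = NA_real_)) |>
    dplyr::select("type", "class", "atom_1", "atom_2", "atom_3",
                  "value", "sigma")
}

#' @exportS3Method broom::glance
glance.sf4_restraints <- function(x, ...) {
  tibble::tibble(
    comp_id = x$comp_id, label = x$label,
    bond = x$bonds$value[1], bond_sigma = x$bonds$sigma[1],
    angle_fesfe = x$angles$value[x$angles$class == "Fe-S-Fe"][1],
    angle_sfes = x$angles$value[x$angles$class == "S-Fe-S"][1],
    n_bonds = nrow(x$bonds), n_angles = nrow(x$angles),
    n_chirals = nrow(x$chirals))
}

# ---- equality used by round-trip contracts ---------------------------------

#' Compare two restraint sets at printed precision
#'
#' Values are compared at the file precision (3 decimals for Angstrom, 2
#' for degrees); atom names and chiral signs exactly.
#'
#' @param a,b `sf4_restraints` objects.
#' @return `TRUE` or `FALSE`.
#' @export
restraints_equal <- function(a, b) {
  isTRUE(a$comp_id == b$comp_id) &&
    identical(a$bonds$atom_1, b$bonds$atom_1) &&
    identical(a$bonds$atom_2, b$bonds$atom_2) &&
    all(round(a$bonds$value, 3) == round(b$bonds$value, 3)) &&
    all(round(a$bonds$sigma, 3) == round(b$bonds$sigma, 3)) &&
    identical(a$angles$atom_1, b$angles$atom_1) &&
    identical(a$angles$atom_2, b$angles$atom_2) &&
    identical(a$angles$atom_3, b$angles$atom_3) &&
    all(round(a$angles$value, 2) == round(b$angles$value, 2)) &&
    all(round(a$angles$sigma, 2) == round(b$angles$sigma, 2)) &&
    identical(a$chirals$center, b$chirals$center) &&
    identical(a$chirals$sign, b$chirals$sign)
}
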