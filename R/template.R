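# Ideal-coordinate construction for SF4.
#
# The cluster is parameterized as two concentric, oppositely oriented
# regular tetrahedra: the irons at a * (+-1, +-1, +-1) vertices with an
# even number of minus signs, the sulfurs at the inverted vertices scaled
# by b. S_i sits antipodal to FE_i, so each iron bonds the other three
# sulfurs and the bond graph is the cubane graph by construction. Closed
# forms for the three internal parameter classes:
#
#   bond      d        = sqrt((a+b)^2 + 2 (a-b)^2)
#   Fe-S-Fe   theta1   = 2 asin(sqrt(2) a / d)
#   S-Fe-S    theta2   = 2 asin(sqrt(2) b / d)
#
# a = b recovers the perfect cube (d = 2a, both angle classes 90 degrees).

.fe_signs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

#' Restraint targets for template construction
#'
#' Defaults are the small-molecule (CSD, S-linked, R <= 0.05) means: bond
#' 2.289 A, Fe-S-Fe 73.66 deg, S-Fe-S 104.18 deg, coordinating Fe-S_AA
#' bond 2.268 A.
#'
#' @param bond Target S-Fe bond length (Angstrom).
#' @param angle_fesfe Target Fe-S-Fe angle (degrees).
#' @param angle_sfes Target S-Fe-S angle (degrees).
#' @param link_bond Target Fe-S_AA coordination bond (Angstrom).
#' @return A named list of class `sf4_template_params`.
#' @export
template_params <- function(bond = 2.289, angle_fesfe = 73.66,
                            angle_sfes = 104.18, link_bond = 2.268) {
  stopifnot(bond > 0, link_bond > 0,
            angle_fesfe > 0, angle_fesfe < 180,
            angle_sfes > 0, angle_sfes < 180)
  structure(list(bond = bond, angle_fesfe = angle_fesfe,
                 angle_sfes = angle_sfes, link_bond = link_bond),
            class = "sf4_template_params")
}

.template_from_scales <- function(a, b) {
  fes <- a * .fe_signs()
  ss <- -b * .fe_signs()
  atom_table(
    atom_name = c(canonical_fe_names(), canonical_s_names()),
    element = rep(c("Fe", "S"), each = 4),
    x = c(fes[, 1], ss[, 1]), y = c(fes[, 2], ss[, 2]),
    z = c(fes[, 3], ss[, 3]),
    residue_name = "SF4", chain_id = "A", residue_number = 1L,
    record = "HETATM")
}

.scales_to_internal <- function(a, b) {
  d <- sqrt((a + b)^2 + 2 * (a - b)^2)
  c(bond = d,
    angle_fesfe = 2 * asin(min(1, sqrt(2) * a / d)) * 180 / pi,
    angle_sfes = 2 * asin(min(1, sqrt(2) * b / d)) * 180 / pi)
}

#' Build the ideal cubic SF4 template
#'
#' Eight atoms at alternating vertices of a perfect cube: all 12 Fe-S
#' bonds equal the edge length and all 24 internal angles are exactly 90
#' degrees. This is the geometry implied by legacy monomer-library
#' restraints (edge 2.135 A).
#'
#' @param bond Cube edge = Fe-S bond length (Angstrom).
#' @return An atom tibble of class `sf4_template`, centered at the origin.
#' @export
build_cubic <- function(bond = 2.135) {
  if (!is.numeric(bond) || length(bond) != 1L || !is.finite(bond) ||
      bond <= 0) {
    stop("invalid parameter: bond length must be a positive number",
         call. = FALSE)
  }
  a <- bond / 2
  out <- .template_from_scales(a, a)
  structure(out,
            class = c("sf4_template", class(out)),
            geometry = "cubic",
            scales = c(a = a, b = a),
            params = template_params(bond = bond, angle_fesfe = 90,
                                     angle_sfes = 90),
            residuals = c(bond = 0, angle_fesfe = 0, angle_sfes = 0))
}

#' Build the ideal rhomboid SF4 template
#'
#' Fits the two tetrahedron scales (a for Fe, b for S) to the three
#' internal targets by unweighted least squares (residuals in Angstrom
#' and degrees on equal footing), starting from the closed-form solution.
#' The small-molecule targets are mutually consistent to about 1e-4 A, so
#' the fit is effectively exact; a target triple that cannot be realized
#' by any pair of concentric tetrahedra (residual above tolerance) raises
#' a geometry-infeasible error reporting the residuals.
#'
#' @param params An [template_params()] list.
#' @param tol_bond Feasibility tolerance on the bond residual (Angstrom).
#' @param tol_angle Feasibility tolerance on each angle residual (degrees).
#' @return An atom tibble of class `sf4_template`, centered at the origin,
#'   with the fitted scales and residuals attached as attributes.
#' @export
build_rhomboid <- function(params = template_params(), tol_bond = 0.005,
                           tol_angle = 0.05) {
  stopifnot(inherits(params, "sf4_template_params"))
  target <- c(bond = params$bond, angle_fesfe = params$angle_fesfe,
              angle_sfes = params$angle_sfes)
  h1 <- sin(params$angle_fesfe * pi / 360) / sqrt(2)
  h2 <- sin(params$angle_sfes * pi / 360) / sqrt(2)
  start <- c(params$bond * h1, params$bond * h2)
  obj <- function(p) {
    if (any(p <= 0)) return(1e6)
    sum((.scales_to_internal(p[1], p[2]) - target)^2)
  }
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  a <- fit$par[1]
  b <- fit$par[2]
  resid <- .scales_to_internal(a, b) - target
  if (abs(resid["bond"]) > tol_bond || any(abs(resid[2:3]) > tol_angle)) {
    stop("geometry-infeasible: no pair of concentric tetrahedra realizes ",
         "the targets (residuals: bond ", signif(resid["bond"], 3),
         " A, Fe-S-Fe ", signif(resid["angle_fesfe"], 3),
         " deg, S-Fe-S ", signif(resid["angle_sfes"], 3), " deg)",
         call. = FALSE)
  }
  out <- .template_from_scales(a, b)
  structure(out,
            class = c("sf4_template", class(out)),
            geometry = if (isTRUE(all.equal(a, b, tolerance = 1e-8)))
              "cubic" else "rhomboid",
            scales = c(a = a, b = b),
            params = params,
            residuals = resid)
}

#' Place axial coordinating-sulfur sites on a template
#'
#' For each iron, one ligand site at `link_bond` Angstrom along its local
#' threefold axis: the direction from the centroid of the iron's three
#' bonded sulfurs through the iron, pointing away from the cluster. These
#' are the idealized positions of the cysteine SG sulfurs.
#'
#' @param template An `sf4_template`.
#' @param link_bond Fe-S_AA distance (Angstrom).
#' @return The template with a `ligand_sites` attribute: a tibble with one
#'   site per iron (`fe_atom`, `x`, `y`, `z`).
#' @export
place_ligand_sites <- function(template, link_bond = 2.268) {
  cl <- validate_cluster(template)
  g <- .cluster_adjacency(cl)
  fexyz <- .atom_xyz(g$fe)
  sxyz <- .atom_xyz(g$s)
  sites <- purrr::map_dfr(1:4, function(i) {
    cen <- colMeans(sxyz[g$adj[i, ], , drop = FALSE])
    u <- fexyz[i, ] - cen
    u <- u / sqrt(sum(u^2))
    p <- fexyz[i, ] + link_bond * u
    tibble::tibble(fe_atom = g$fe$atom_name[i], x = p[1], y = p[2], z = p[3])
  })
  attr(template, "ligand_sites") <- sites
  template
}

#' @export
print.sf4_template <- function(x, ...) {
  prof <- cluster_profile(x)
  means <- tapply(prof$value, prof$class, mean)
  cat("SF4 ideal template (", attr(x, "geometry"), ")\n", sep = "")
  cat(sprintf("  mean S-Fe   %.4f A\n", means[["S-Fe"]]))
  cat(sprintf("  mean Fe-S-Fe %.3f deg\n", means[["Fe-S-Fe"]]))
  cat(sprintf("  mean S-Fe-S  %.3f deg\n", means[["S-Fe-S"]]))
  if (!is.null(attr(x, "ligand_sites"))) {
    cat("  4 axial ligand sites placed\n")
  }
  NextMethod()
}

#' @exportS3Method broom::glance
glance.sf4_template <- function(x, ...) {
  sc <- attr(x, "scales")
  resid <- attr(x, "residuals")
  p <- attr(x, "params")
  tibble::tibble(
    geometry = attr(x, "geometry"),
    scale_fe = unname(sc["a"]),
    scale_s = unname(sc["b"]),
    target_bond = p$bond,
    target_angle_fesfe = p$angle_fesfe,
    target_angle_sfes = p$angle_sfes,
    resid_bond = unname(resid["bond"]),
    resid_angle_fesfe = unname(resid["angle_fesfe"]),
    resid_angle_sfes = unname(resid["angle_sfes"]))
}

#' @exportS3Method broom::tidy
tidy.sf4_template <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "sf4_template")
  out
}
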