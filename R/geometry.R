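# Exact geometric measurement for Fe4S4 cubane clusters.
#
# The cluster is eight atoms at alternating vertices of a (distorted) cube:
# four irons and four inorganic sulfurs, every bond heterogeneous, so the
# bond graph is K4,4 minus a perfect matching (12 edges, each Fe bonded to
# exactly three S and vice versa).

#' Canonical SF4 atom names
#'
#' The wwPDB chemical component SF4 names its atoms FE1--FE4 and S1--S4.
#' All naming, restraint and relabeling machinery in this package is keyed
#' to these eight names.
#'
#' @return Character vector of canonical names.
#' @export
canonical_atom_names <- function() c(canonical_fe_names(), canonical_s_names())

#' @rdname canonical_atom_names
#' @export
canonical_fe_names <- function() paste0("FE", 1:4)

#' @rdname canonical_atom_names
#' @export
canonical_s_names <- function() paste0("S", 1:4)

#' Default Fe-S bond cutoff (Angstrom)
#'
#' An Fe/S pair is considered bonded when closer than this distance. The
#' default, 2.41 A, is the mean small-molecule Fe-S bond (2.289 A) plus
#' five standard deviations (5 x 0.024 A): wide enough to cover the
#' observed spread of deposited cluster geometries, but far below the
#' ~3.6 A S-S nonbonded contacts inside the cluster.
#'
#' @return Cutoff in Angstrom.
#' @export
default_bond_cutoff <- function() 2.289 + 5 * 0.024

.as_point <- function(p, arg = deparse(substitute(p))) {
  p <- suppressWarnings(as.numeric(p))
  if (length(p) != 3L || anyNA(p) || !all(is.finite(p))) {
    stop("invalid coordinates for '", arg, "': need 3 finite numbers",
         call. = FALSE)
  }
  p
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric length-3 coordinates in Angstrom.
#' @return Distance in Angstrom.
#' @export
measure_distance <- function(a, b) {
  a <- .as_point(a, "a")
  b <- .as_point(b, "b")
  sqrt(sum((a - b)^2))
}

#' Angle at a vertex
#'
#' @param a,c Numeric length-3 coordinates of the two arms.
#' @param vertex Numeric length-3 coordinates of the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
measure_angle <- function(a, vertex, c) {
  a <- .as_point(a, "a")
  v <- .as_point(vertex, "vertex")
  c <- .as_point(c, "c")
  u <- a - v
  w <- c - v
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) {
    stop("degenerate angle: zero-length arm at the vertex", call. = FALSE)
  }
  cosang <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Signed chiral volume at a center
#'
#' Scalar triple product (n1 - center) . ((n2 - center) x (n3 - center)).
#' With the neighbours ordered by ascending canonical atom name the sign is
#' a deterministic handedness indicator: it flips under mirror reflection
#' of the coordinates.
#'
#' @param center Numeric length-3 coordinates of the central atom.
#' @param n1,n2,n3 Neighbour coordinates, ordered by ascending canonical
#'   atom name.
#' @return Signed volume in cubic Angstrom.
#' @export
chiral_volume <- function(center, n1, n2, n3) {
  center <- .as_point(center, "center")
  v1 <- .as_point(n1, "n1") - center
  v2 <- .as_point(n2, "n2") - center
  v3 <- .as_point(n3, "n3") - center
  sum(v1 * (c(
    v2[2] * v3[3] - v2[3] * v3[2],
    v2[3] * v3[1] - v2[1] * v3[3],
    v2[1] * v3[2] - v2[2] * v3[1]
  )))
}

# ---- cluster container ------------------------------------------------------

#' Build an atom table
#'
#' The package-wide model container is a plain tibble with one row per atom.
#'
#' @param atom_name,element Character vectors.
#' @param x,y,z Coordinates in Angstrom.
#' @param residue_name,chain_id Character.
#' @param residue_number Integer.
#' @param record "ATOM" or "HETATM".
#' @param occupancy,b_factor Numeric.
#' @return A tibble with one row per atom.
#' @export
atom_table <- function(atom_name, element, x, y, z,
                       residue_name = "SF4", chain_id = "A",
                       residue_number = 1L, record = "HETATM",
                       occupancy = 1, b_factor = 20) {
  tibble::tibble(
    record = record,
    atom_name = toupper(atom_name),
    element = element,
    residue_name = residue_name,
    chain_id = chain_id,
    residue_number = as.integer(residue_number),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    occupancy = occupancy,
    b_factor = b_factor
  )
}

.atom_xyz <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z")]))
}

#' Validate a cluster atom table
#'
#' Checks that `cluster` holds exactly the eight atoms of one SF4
#' occurrence (4 Fe, 4 S) with finite coordinates, and returns it ordered
#' by canonical atom name when the names are canonical.
#'
#' @param cluster An atom tibble (8 rows).
#' @return The validated cluster tibble.
#' @export
validate_cluster <- function(cluster) {
  stopifnot(is.data.frame(cluster))
  cluster <- tibble::as_tibble(cluster)
  n_fe <- sum(cluster$element == "Fe")
  n_s <- sum(cluster$element == "S")
  if (n_fe != 4L || n_s != 4L) {
    missing <- setdiff(canonical_atom_names(), cluster$atom_name)
    stop("incomplete cluster: found ", n_fe, " Fe and ", n_s, " S atoms",
         if (length(missing)) paste0(" (missing: ",
                                     paste(missing, collapse = ", "), ")"),
         call. = FALSE)
  }
  xyz <- .atom_xyz(cluster)
  if (!all(is.finite(xyz))) {
    stop("invalid coordinates: non-finite cluster coordinates", call. = FALSE)
  }
  if (setequal(cluster$atom_name, canonical_atom_names())) {
    cluster <- cluster[match(canonical_atom_names(), cluster$atom_name), ]
  }
  cluster
}

# Fe x S adjacency (4 x 4 logical) under the distance criterion, with the
# cubane-topology check: every Fe bonded to exactly 3 S and vice versa.
.cluster_adjacency <- function(cluster, bond_cutoff = default_bond_cutoff()) {
  fe <- cluster[cluster$element == "Fe", ]
  s <- cluster[cluster$element == "S", ]
  fexyz <- .atom_xyz(fe)
  sxyz <- .atom_xyz(s)
  d <- sqrt(outer(rowSums(fexyz^2), rowSums(sxyz^2), "+") -
              2 * fexyz %*% t(sxyz))
  adj <- d < bond_cutoff
  if (!all(rowSums(adj) == 3L) || !all(colSums(adj) == 3L)) {
    stop("cluster bond graph is not a cubane: expected each Fe bonded to ",
         "exactly 3 S under the ", format(bond_cutoff),
         " A cutoff", call. = FALSE)
  }
  list(fe = fe, s = s, adj = adj, dist = d)
}

#' Measure the full geometry profile of a cluster
#'
#' Computes the 12 Fe-S bond lengths, the 12 Fe-S-Fe angles (three per
#' sulfur vertex) and the 12 S-Fe-S angles (three per iron vertex) of a
#' complete cluster, plus, when coordination links are supplied, one
#' Fe-S_AA bond and three S-Fe-S_AA angles per link (S_AA being the
#' coordinating amino-acid sulfur, typically cysteine SG).
#'
#' Connectivity is derived from the distance criterion, not from atom
#' names, so the profile is invariant under renaming and under rigid
#' motion of the model.
#'
#' @param cluster An 8-atom cluster tibble (see [find_clusters()]).
#' @param links Optional link table from [detect_links()].
#' @param bond_cutoff Fe-S bond criterion in Angstrom.
#' @return A tibble with columns `class` (one of `"S-Fe"`, `"Fe-S-Fe"`,
#'   `"S-Fe-S"`, `"Fe-S_AA"`, `"S-Fe-S_AA"`), `value` (Angstrom or
#'   degrees), the atom names involved, and `partner_residue` for link
#'   measurements.
#' @export
cluster_profile <- function(cluster, links = NULL,
                            bond_cutoff = default_bond_cutoff()) {
  cluster <- validate_cluster(cluster)
  g <- .cluster_adjacency(cluster, bond_cutoff)
  fe <- g$fe
  s <- g$s
  fexyz <- .atom_xyz(fe)
  sxyz <- .atom_xyz(s)

  rows <- list()
  # 12 Fe-S bonds
  for (i in 1:4) {
    for (j in which(g$adj[i, ])) {
      rows[[length(rows) + 1L]] <- list(
        class = "S-Fe", value = g$dist[i, j],
        atom_1 = s$atom_name[j], atom_2 = fe$atom_name[i], atom_3 = NA_character_,
        partner_residue = NA_character_)
    }
  }
  # 12 Fe-S-Fe angles: three per S vertex
  for (j in 1:4) {
    nb <- which(g$adj[, j])
    for (pr in utils::combn(nb, 2, simplify = FALSE)) {
      rows[[length(rows) + 1L]] <- list(
        class = "Fe-S-Fe",
        value = measure_angle(fexyz[pr[1], ], sxyz[j, ], fexyz[pr[2], ]),
        atom_1 = fe$atom_name[pr[1]], atom_2 = s$atom_name[j],
        atom_3 = fe$atom_name[pr[2]], partner_residue = NA_character_)
    }
  }
  # 12 S-Fe-S angles: three per Fe vertex
  for (i in 1:4) {
    nb <- which(g$adj[i, ])
    for (pr in utils::combn(nb, 2, simplify = FALSE)) {
      rows[[length(rows) + 1L]] <- list(
        class = "S-Fe-S",
        value = measure_angle(sxyz[pr[1], ], fexyz[i, ], sxyz[pr[2], ]),
        atom_1 = s$atom_name[pr[1]], atom_2 = fe$atom_name[i],
        atom_3 = s$atom_name[pr[2]], partner_residue = NA_character_)
    }
  }

  if (!is.null(links) && nrow(links) > 0) {
    for (k in seq_len(nrow(links))) {
      li <- links[k, ]
      i <- match(li$fe_atom, fe$atom_name)
      if (is.na(i)) {
        stop("orphan link: iron '", li$fe_atom,
             "' is not an atom of this cluster", call. = FALSE)
      }
      fpos <- fexyz[i, ]
      gpos <- c(li$sg_x, li$sg_y, li$sg_z)
      rows[[length(rows) + 1L]] <- list(
        class = "Fe-S_AA", value = measure_distance(fpos, gpos),
        atom_1 = fe$atom_name[i], atom_2 = li$partner_atom,
        atom_3 = NA_character_, partner_residue = li$partner_residue)
      for (j in which(g$adj[i, ])) {
        rows[[length(rows) + 1L]] <- list(
          class = "S-Fe-S_AA",
          value = measure_angle(sxyz[j, ], fpos, gpos),
          atom_1 = s$atom_name[j], atom_2 = fe$atom_name[i],
          atom_3 = li$partner_atom, partner_residue = li$partner_residue)
      }
    }
  }

  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  class(out) <- c("sf4_profile", class(out))
  out
}
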