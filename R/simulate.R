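# Seeded synthetic-structure generator. Every other module is testable
# against corpora built here, with known ground truth: cluster shape,
# applied name permutation, and coordinating cysteine placement.
#
# Noise is applied in internal-coordinate space: per model, one bond and
# two angle targets are drawn around the configured means and the cluster
# is rebuilt by the least-squares two-tetrahedra fit. The drawn bond is
# reproduced exactly (scale is a free parameter of the construction), so
# pooled mined means are unbiased estimates of the generator parameters;
# drawn angle pairs are projected onto the feasible one-parameter shape
# family. A Cartesian-jitter mode exists for robustness tests.

#' Configuration for the synthetic generator
#'
#' Defaults are the small-molecule S-linked study conditions: rhomboid
#' geometry with bond 2.289 (sigma 0.024) A, Fe-S-Fe 73.66 (0.87) deg,
#' S-Fe-S 104.18 (1.24) deg, and cysteine SG partners at 2.268 (0.017) A
#' when requested. Cubic models use bond 2.135 (0.020) A.
#'
#' @param n_models Number of models.
#' @param seed Master seed; per-model substreams are derived from
#'   (seed, index) so generation is reproducible model by model.
#' @param geometry Base geometry, `"rhomboid"` or `"cubic"`.
#' @param bond_sigma,angle_sigma_fesfe,angle_sigma_sfes Internal-coordinate
#'   noise (Angstrom / degrees).
#' @param coord_noise Extra isotropic Cartesian jitter sigma (Angstrom).
#' @param permute_fraction Fraction of models whose atom names receive a
#'   random chirality-breaking permutation (the observable misnaming
#'   condition: chirality-preserving relabelings are equally correct
#'   namings of a symmetric cluster and leave no signal).
#' @param cubic_fraction Fraction of models built cubic regardless of the
#'   base geometry.
#' @param with_cysteines Add four CYS residues whose SG sulfurs sit on the
#'   iron threefold axes.
#' @param link_bond,link_bond_sigma Fe-SG placement distance (Angstrom).
#' @param resolution_range,r_work_range,rfree_gap_range,completeness_range
#'   Metadata draw ranges for corpus generation.
#' @return A list of class `sf4_sim_config`.
#' @export
simulation_config <- function(n_models = 1L, seed = 1L,
                              geometry = c("rhomboid", "cubic"),
                              bond_sigma = 0.024,
                              angle_sigma_fesfe = 0.87,
                              angle_sigma_sfes = 1.24,
                              coord_noise = 0,
                              permute_fraction = 0,
                              cubic_fraction = 0,
                              with_cysteines = FALSE,
                              link_bond = 2.268,
                              link_bond_sigma = 0.017,
                              resolution_range = c(1.0, 3.5),
                              r_work_range = c(0.12, 0.28),
                              rfree_gap_range = c(0.02, 0.06),
                              completeness_range = c(0.92, 1.0)) {
  geometry <- match.arg(geometry)
  stopifnot(n_models >= 1, bond_sigma >= 0, angle_sigma_fesfe >= 0,
            angle_sigma_sfes >= 0, coord_noise >= 0,
            permute_fraction >= 0, permute_fraction <= 1,
            cubic_fraction >= 0, cubic_fraction <= 1)
  structure(list(
    n_models = as.integer(n_models), seed = as.integer(seed),
    geometry = geometry, bond_sigma = bond_sigma,
    angle_sigma_fesfe = angle_sigma_fesfe,
    angle_sigma_sfes = angle_sigma_sfes,
    coord_noise = coord_noise, permute_fraction = permute_fraction,
    cubic_fraction = cubic_fraction, with_cysteines = with_cysteines,
    link_bond = link_bond, link_bond_sigma = link_bond_sigma,
    resolution_range = resolution_range, r_work_range = r_work_range,
    rfree_gap_range = rfree_gap_range,
    completeness_range = completeness_range),
    class = "sf4_sim_config")
}

# Deterministic 32-bit substream seed from (seed, index).
.substream_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

.random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate one synthetic cluster model
#'
#' Builds the configured geometry with internal-coordinate noise, applies
#' a random rigid motion, optional Cartesian jitter, optional atom-name
#' permutation (uniform over the 12 chirality-breaking relabelings) and
#' optional cysteine SG placement. Fully reproducible from
#' (config$seed, index).
#'
#' @param config An [simulation_config()].
#' @param index Model index (1-based).
#' @return A list: `model` (atom tibble), `truth` (geometry label, drawn
#'   internal targets, applied permutation or NULL, link distances).
#' @export
generate_cluster_model <- function(config, index = 1L) {
  stopifnot(inherits(config, "sf4_sim_config"))
  set.seed(.substream_seed(config$seed, index))

  cubic <- if (config$cubic_fraction > 0) {
    stats::runif(1) < config$cubic_fraction
  } else {
    config$geometry == "cubic"
  }

  repeat {
    if (cubic) {
      bond <- stats::rnorm(1, 2.135, min(config$bond_sigma, 0.020))
      t1 <- 90
      t2 <- 90
    } else {
      bond <- stats::rnorm(1, 2.289, config$bond_sigma)
      t1 <- stats::rnorm(1, 73.66, config$angle_sigma_fesfe)
      t2 <- stats::rnorm(1, 104.18, config$angle_sigma_sfes)
    }
    if (bond > 0.5 && t1 > 10 && t1 < 170 && t2 > 10 && t2 < 170) break
  }
  params <- template_params(bond = bond, angle_fesfe = t1, angle_sfes = t2,
                            link_bond = config$link_bond)
  # wide tolerances: drawn angle pairs are projected onto the feasible
  # shape family, never rejected
  tmpl <- build_rhomboid(params, tol_bond = 1, tol_angle = 30)
  tmpl <- place_ligand_sites(tmpl, link_bond = config$link_bond)
  sites <- attr(tmpl, "ligand_sites")

  model <- atom_table(
    atom_name = tmpl$atom_name, element = tmpl$element,
    x = tmpl$x, y = tmpl$y, z = tmpl$z,
    residue_name = "SF4", chain_id = "A", residue_number = 500L)

  links_truth <- NULL
  if (config$with_cysteines) {
    cys <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      fe <- model[model$atom_name == sites$fe_atom[i], ]
      u <- c(sites$x[i] - fe$x, sites$y[i] - fe$y, sites$z[i] - fe$z)
      u <- u / sqrt(sum(u^2))
      d <- stats::rnorm(1, config$link_bond, config$link_bond_sigma)
      p <- c(fe$x, fe$y, fe$z) + d * u
      atom_table(atom_name = "SG", element = "S", x = p[1], y = p[2],
                 z = p[3], residue_name = "CYS", chain_id = "A",
                 residue_number = 100L + i, record = "ATOM")
    })
    links_truth <- sqrt((cys$x - model$x[match(sites$fe_atom,
                                               model$atom_name)])^2 +
                          (cys$y - model$y[match(sites$fe_atom,
                                                 model$atom_name)])^2 +
                          (cys$z - model$z[match(sites$fe_atom,
                                                 model$atom_name)])^2)
    model <- dplyr::bind_rows(model, cys)
  }

  # random rigid motion of the whole model
  R <- .random_rotation()
  tr <- stats::runif(3, -20, 20)
  xyz <- .atom_xyz(model) %*% t(R)
  model$x <- xyz[, 1] + tr[1]
  model$y <- xyz[, 2] + tr[2]
  model$z <- xyz[, 3] + tr[3]

  if (config$coord_noise > 0) {
    n <- nrow(model)
    model$x <- model$x + stats::rnorm(n, 0, config$coord_noise)
    model$y <- model$y + stats::rnorm(n, 0, config$coord_noise)
    model$z <- model$z + stats::rnorm(n, 0, config$coord_noise)
  }

  permutation <- NULL
  if (config$permute_fraction > 0 &&
      stats::runif(1) < config$permute_fraction) {
    all24 <- enumerate_relabelings(chirality_preserving = FALSE)
    proper <- enumerate_relabelings(chirality_preserving = TRUE)
    ids <- vapply(proper, paste, "", collapse = " ")
    breaking <- Filter(function(m) !(paste(m, collapse = " ") %in% ids),
                       all24)
    permutation <- breaking[[sample.int(length(breaking), 1)]]
    idx <- model$residue_name == "SF4"
    model$atom_name[idx] <- unname(permutation[model$atom_name[idx]])
  }

  list(model = model,
       truth = list(index = index,
                    geometry = if (cubic) "cubic" else "rhomboid",
                    bond = bond, angle_fesfe = t1, angle_sfes = t2,
                    permutation = permutation,
                    link_distances = links_truth))
}

#' Generate a synthetic corpus on disk
#'
#' Writes `n_models` PDB files plus `metadata.csv` (entry id, file,
#' resolution and refinement statistics drawn from the configured ranges)
#' and `truth.json` (the per-model ground truth). Deterministic under the
#' master seed.
#'
#' @param config An [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The metadata tibble, invisibly; files are written under `dir`.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "sf4_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- vector("list", config$n_models)
  files <- character(config$n_models)
  for (i in seq_len(config$n_models)) {
    gen <- generate_cluster_model(config, i)
    files[i] <- sprintf("syn%04d.pdb", i)
    write_structure(gen$model, file.path(dir, files[i]))
    truths[[i]] <- gen$truth
  }
  set.seed(.substream_seed(config$seed, 0L))
  n <- config$n_models
  meta <- tibble::tibble(
    entry_id = sprintf("SYN%04d", seq_len(n)),
    file = files,
    resolution = round(stats::runif(n, config$resolution_range[1],
                                    config$resolution_range[2]), 2),
    r_work = round(stats::runif(n, config$r_work_range[1],
                                config$r_work_range[2]), 4),
    completeness = round(stats::runif(n, config$completeness_range[1],
                                      config$completeness_range[2]), 4),
    twinned = FALSE,
    has_structure_factors = TRUE)
  meta$r_free <- round(meta$r_work +
                         stats::runif(n, config$rfree_gap_range[1],
                                      config$rfree_gap_range[2]), 4)
  meta$r_factor <- meta$r_work
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  jsonlite::write_json(
    lapply(truths, function(t) {
      t$permutation <- if (is.null(t$permutation)) NULL else
        as.list(t$permutation)
      t
    }),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(meta)
}

#' Generate an in-memory corpus
#'
#' Like [generate_corpus()] but returning the corpus tibble directly
#' (models as a list-column) without touching the filesystem. The draws
#' are identical to the on-disk variant.
#'
#' @param config An [simulation_config()].
#' @return A corpus tibble with a `model` list-column and a `truth`
#'   list-column.
#' @export
generate_corpus_memory <- function(config) {
  stopifnot(inherits(config, "sf4_sim_config"))
  gens <- lapply(seq_len(config$n_models), function(i) {
    generate_cluster_model(config, i)
  })
  set.seed(.substream_seed(config$seed, 0L))
  n <- config$n_models
  meta <- tibble::tibble(
    entry_id = sprintf("SYN%04d", seq_len(n)),
    file = sprintf("syn%04d.pdb", seq_len(n)),
    resolution = round(stats::runif(n, config$resolution_range[1],
                                    config$resolution_range[2]), 2),
    r_work = round(stats::runif(n, config$r_work_range[1],
                                config$r_work_range[2]), 4),
    completeness = round(stats::runif(n, config$completeness_range[1],
                                      config$completeness_range[2]), 4),
    twinned = FALSE,
    has_structure_factors = TRUE)
  meta$r_free <- round(meta$r_work +
                         stats::runif(n, config$rfree_gap_range[1],
                                      config$rfree_gap_range[2]), 4)
  meta$r_factor <- meta$r_work
  meta$model <- lapply(gens, `[[`, "model")
  meta$truth <- lapply(gens, `[[`, "truth")
  meta
}
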