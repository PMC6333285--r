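# Shared fixtures and small independent oracles used across the suite.

# Independent permutation generator (recursive, unlike the package's
# loop-based one).
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Parity of a permutation vector (+1 even, -1 odd), by inversion count.
perm_sign <- function(p) {
  inv <- 0L
  for (i in seq_along(p)) {
    inv <- inv + sum(p[seq_len(i - 1L)] > p[i])
  }
  if (inv %% 2L == 0L) 1L else -1L
}

# Apply a rigid motion (random rotation + translation) to an atom tibble.
rigid_motion <- function(model, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(m))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- runif(3, -30, 30)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + tr[1]
  model$y <- xyz[, 2] + tr[2]
  model$z <- xyz[, 3] + tr[3]
  model
}

# Mirror an atom tibble through the xy plane.
mirror_model <- function(model) {
  model$z <- -model$z
  model
}

# Apply a relabeling (named chr vector observed -> canonical) to the atom
# names of the SF4 residue of a model.
apply_relabeling <- function(model, relabeling) {
  idx <- model$residue_name == "SF4"
  model$atom_name[idx] <- unname(relabeling[model$atom_name[idx]])
  model
}

# The 12 chirality-breaking relabelings (complement of the proper 12).
breaking_relabelings <- function() {
  all24 <- enumerate_relabelings(chirality_preserving = FALSE)
  ids <- vapply(enumerate_relabelings(chirality_preserving = TRUE),
                paste, "", collapse = " ")
  Filter(function(m) !(paste(m, collapse = " ") %in% ids), all24)
}

# Gaussian coordinate jitter.
jitter_model <- function(model, sd, seed = 1) {
  set.seed(seed)
  n <- nrow(model)
  model$x <- model$x + rnorm(n, 0, sd)
  model$y <- model$y + rnorm(n, 0, sd)
  model$z <- model$z + rnorm(n, 0, sd)
  model
}

# A template plus its four axial cysteine SG atoms as a full model tibble.
template_with_cys <- function(template = build_rhomboid(),
                              link_bond = 2.268) {
  tl <- place_ligand_sites(template, link_bond = link_bond)
  sites <- attr(tl, "ligand_sites")
  cys <- atom_table(
    atom_name = rep("SG", 4), element = rep("S", 4),
    x = sites$x, y = sites$y, z = sites$z,
    residue_name = "CYS", chain_id = "A",
    residue_number = 101:104, record = "ATOM")
  sf4 <- atom_table(
    atom_name = template$atom_name, element = template$element,
    x = template$x, y = template$y, z = template$z,
    residue_name = "SF4", chain_id = "A", residue_number = 500L)
  dplyr::bind_rows(sf4, cys)
}
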