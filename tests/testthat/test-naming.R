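test_that("brute force over all 576 bijections finds 24 relabelings, 12 proper", {
  # independent oracle: recursive permutation generator + explicit
  # adjacency check (FE_i bonded to S_j iff i != j), with chirality judged
  # by permutation parity rather than superposition
  perms <- perms_of(1:4)
  n_adj <- 0L
  n_even <- 0L
  for (pf in perms) {
    for (ps in perms) {
      ok <- TRUE
      for (i in 1:4) {
        for (j in 1:4) {
          if ((i != j) != (pf[i] != ps[j])) ok <- FALSE
        }
      }
      if (ok) {
        n_adj <- n_adj + 1L
        if (perm_sign(pf) == 1L) n_even <- n_even + 1L
      }
    }
  }
  expect_equal(n_adj, 24L)
  expect_equal(n_even, 12L)

  all24 <- enumerate_relabelings(chirality_preserving = FALSE)
  proper <- enumerate_relabelings(chirality_preserving = TRUE)
  expect_length(all24, 24L)
  expect_length(proper, 12L)
  # identity first in both
  expect_identical(unname(all24[[1]]), names(all24[[1]]))
  expect_identical(unname(proper[[1]]), names(proper[[1]]))
  # the proper set is exactly the even-parity set
  even_ids <- vapply(proper, paste, "", collapse = " ")
  for (m in all24) {
    pf <- match(m[canonical_fe_names()], canonical_fe_names())
    expect_equal(paste(m, collapse = " ") %in% even_ids,
                 perm_sign(pf) == 1L)
  }
})

test_that("unperturbed template maps to itself with zero rmsd", {
  m <- best_mapping(build_rhomboid())
  expect_true(m$identity)
  expect_true(m$rotation_proper)
  expect_lt(m$rmsd, 1e-9)
  expect_false(is_misnamed(m))
})

test_that("superposition rmsd agrees with an independent implementation", {
  t <- build_rhomboid()
  noisy <- jitter_model(rigid_motion(t, 3), 0.1, seed = 11)
  m <- best_mapping(noisy)
  # oracle: bio3d least-squares fit of the same (identity) pairing
  # (suppressed warning: fit over all atoms without an index subset)
  fit <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(as.matrix(noisy[, c("x", "y", "z")]))),
    mobile = as.vector(t(as.matrix(t[, c("x", "y", "z")])))))
  oracle <- bio3d::rmsd(
    as.vector(t(as.matrix(noisy[, c("x", "y", "z")]))), fit)
  expect_lt(abs(m$rmsd_identity - oracle), 1e-3)  # bio3d rounds to 3 d.p.
})

test_that("a chirality-breaking swap is recovered and fixable", {
  # swap FE1/FE2 together with S1/S2: adjacency-consistent but odd
  swap <- stats::setNames(canonical_atom_names(), canonical_atom_names())
  swap[c("FE1", "FE2", "S1", "S2")] <- c("FE2", "FE1", "S2", "S1")
  model <- template_with_cys()
  permuted <- apply_relabeling(model, swap)
  cl <- find_clusters(permuted)[[1]]
  m <- best_mapping(cl)
  expect_false(m$identity)
  expect_false(m$rotation_proper)
  expect_lt(m$rmsd, 1e-9)
  expect_gt(m$rmsd_identity, 0.5)
  expect_true(is_misnamed(m))

  # renaming with the returned mapping restores a properly named cluster
  fixed <- rename_atoms(permuted, m)
  m2 <- best_mapping(find_clusters(fixed)[[1]])
  expect_true(m2$identity)
  expect_false(is_misnamed(m2))
  # coordinates untouched, other residues untouched
  expect_equal(fixed[, c("x", "y", "z")], permuted[, c("x", "y", "z")])
  expect_identical(fixed[fixed$residue_name == "CYS", ],
                   permuted[permuted$residue_name == "CYS", ])
})

test_that("chirality-preserving relabelings are equivalent correct namings", {
  # such a relabeling is realized by a rotation, so the identity fits just
  # as well and no misnaming is reported
  t <- build_rhomboid()
  proper <- enumerate_relabelings(chirality_preserving = TRUE)
  model <- template_with_cys()
  for (m in proper[c(3, 7, 12)]) {
    permuted <- apply_relabeling(model, m)
    mp <- best_mapping(find_clusters(permuted)[[1]])
    expect_true(mp$rotation_proper)
    expect_lt(mp$rmsd, 1e-9)
    expect_false(is_misnamed(mp))
  }
})

test_that("mirror-imaged clusters are flagged as inverted chirality", {
  t <- build_rhomboid()
  mirrored <- mirror_model(t)
  prop <- best_mapping(mirrored, relabelings = "proper")
  expect_gt(prop$rmsd, 0.5)
  full <- best_mapping(mirrored)
  expect_false(full$rotation_proper)
  expect_true(full$chirality_flag)
})

test_that("misnaming recovery is robust to coordinate noise and rigid motion", {
  # 100 seeded trials: random chirality-breaking relabeling + 0.05 A noise
  # + random rigid motion; recovery is judged up to the proper symmetry
  # group (the renamed cluster must be proper-equivalent to canonical)
  breaking <- breaking_relabelings()
  set.seed(2026)
  draws <- sample.int(length(breaking), 100, replace = TRUE)
  model0 <- template_with_cys()
  n_ok <- 0L
  for (k in seq_len(100)) {
    permuted <- apply_relabeling(model0, breaking[[draws[k]]])
    noisy <- jitter_model(rigid_motion(permuted, seed = 1000 + k), 0.05,
                          seed = 2000 + k)
    m <- best_mapping(find_clusters(noisy)[[1]])
    fixed <- rename_atoms(noisy, m)
    m2 <- best_mapping(find_clusters(fixed)[[1]])
    if (!m$rotation_proper && is_misnamed(m) && m$rmsd < 0.2 &&
        m2$rotation_proper && !is_misnamed(m2)) {
      n_ok <- n_ok + 1L
    }
  }
  expect_equal(n_ok, 100L)
})

test_that("best_mapping rmsd is invariant under rigid motion", {
  t <- build_rhomboid()
  noisy <- jitter_model(t, 0.05, seed = 5)
  r0 <- best_mapping(noisy)$rmsd_identity
  for (seed in 1:5) {
    expect_equal(best_mapping(rigid_motion(noisy, seed))$rmsd_identity, r0,
                 tolerance = 1e-9)
  }
})

test_that("rename errors are informative", {
  t <- build_rhomboid()
  m <- best_mapping(t)
  model <- template_with_cys()
  m$residue_number <- 999L
  expect_error(rename_atoms(model, m), "no SF4 residue")
  expect_error(best_mapping(t[1:7, ]), "incomplete")
})
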