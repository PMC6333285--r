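test_that("rmsd against the matching set is at numerical-fit level", {
  p <- cluster_profile(build_rhomboid())
  r <- rmsd_to_restraints(p, rhomboid_restraints())
  expect_lt(r$bond_rmsd, 0.005)
  expect_lt(r$angle_rmsd, 0.05)
  expect_equal(r$n_bonds, 12L)
  expect_equal(r$n_angles, 24L)

  pc <- cluster_profile(build_cubic())
  rc <- rmsd_to_restraints(pc, cubic_restraints())
  expect_equal(rc$bond_rmsd, 0)
  expect_lt(rc$angle_rmsd, 1e-9)
})

test_that("rhomboid cluster against cubic targets matches the closed forms", {
  p <- cluster_profile(build_rhomboid())
  r <- rmsd_to_restraints(p, cubic_restraints())
  # all 12 bonds deviate uniformly by 2.289 - 2.135
  expect_equal(r$bond_rmsd, 0.154, tolerance = 0.001)
  # angles: 12 at |104.18 - 90| = 14.18, 12 at |73.66 - 90| = 16.34
  oracle <- sqrt((12 * 14.18^2 + 12 * 16.34^2) / 24)
  expect_equal(r$angle_rmsd, oracle, tolerance = 0.01)
  expect_equal(r$angle_rmsd, 15.30, tolerance = 0.01)
})

test_that("link terms join the rmsd pools when requested", {
  model <- template_with_cys()
  cl <- find_clusters(model)[[1]]
  links <- detect_links(cl, model)
  prof <- cluster_profile(cl, links = links)
  r <- rmsd_to_restraints(prof, rhomboid_restraints(),
                          link = link_definition())
  expect_equal(r$n_bonds, 16L)
  expect_equal(r$n_angles, 36L)
  # ideal placement: link bond deviations are zero, external angles ~0.1
  r_nolink <- rmsd_to_restraints(prof, rhomboid_restraints())
  expect_equal(r_nolink$n_bonds, 12L)
  expect_lt(r$bond_rmsd, 0.005)
})

test_that("sigma weighting rescales deviations by the restraint sigmas", {
  p <- cluster_profile(build_rhomboid())
  raw <- rmsd_to_restraints(p, cubic_restraints())
  wtd <- rmsd_to_restraints(p, cubic_restraints(), sigma_weighted = TRUE)
  expect_equal(wtd$bond_rmsd, raw$bond_rmsd / 0.020, tolerance = 1e-9)
})

test_that("bond rmsd responds exactly to uniform bond inflation", {
  # the cubic template realizes its bond target exactly, so scaling all
  # coordinates by (bond + delta) / bond moves bond_rmsd to exactly delta
  delta <- 0.05
  t <- build_cubic(2.135)
  scale <- (2.135 + delta) / 2.135
  t2 <- t
  t2$x <- t$x * scale
  t2$y <- t$y * scale
  t2$z <- t$z * scale
  r <- rmsd_to_restraints(cluster_profile(t2), cubic_restraints())
  expect_equal(r$bond_rmsd, delta, tolerance = 1e-9)
})

test_that("incomplete profiles are rejected", {
  p <- cluster_profile(build_rhomboid())
  expect_error(rmsd_to_restraints(p[-1, ], rhomboid_restraints()),
               "inconsistent")
})

test_that("classification separates the three cluster conditions", {
  expect_equal(classify_cluster(build_rhomboid()), "rhomboid")
  expect_equal(classify_cluster(build_cubic()), "cubic")

  swap <- stats::setNames(canonical_atom_names(), canonical_atom_names())
  swap[c("FE3", "FE4", "S3", "S4")] <- c("FE4", "FE3", "S4", "S3")
  misnamed <- apply_relabeling(template_with_cys(), swap)
  expect_equal(classify_cluster(find_clusters(misnamed)[[1]]), "misnamed")

  # moderate coordinate noise does not flip the call (0.02 A per
  # coordinate stays well inside both the angle-class separation and the
  # 2.41 A bond criterion)
  for (seed in 1:5) {
    noisy_rh <- jitter_model(build_rhomboid(), 0.02, seed)
    noisy_cu <- jitter_model(build_cubic(), 0.02, seed + 100)
    expect_equal(classify_cluster(noisy_rh), "rhomboid")
    expect_equal(classify_cluster(noisy_cu), "cubic")
  }
})

test_that("corpus report bins by resolution and recovers generator noise", {
  expect_equal(nrow(corpus_report(tibble::tibble(entry_id = character(),
                                                 resolution = numeric(),
                                                 model = list()),
                                  rhomboid_restraints())), 0L)

  # ideal fixtures at assorted resolutions: zero rmsd in every bin
  model <- template_with_cys()
  corpus <- tibble::tibble(
    entry_id = sprintf("E%02d", 1:10),
    resolution = seq(1.1, 3.2, length.out = 10),
    model = replicate(10, model, simplify = FALSE))
  rep <- corpus_report(corpus, rhomboid_restraints())
  expect_true(all(rep$bond_rmsd < 0.005))
  expect_true(all(rep$angle_rmsd < 0.05))
  expect_equal(sum(rep$n), 10L)

  # synthetic noisy corpus: per-bin bond rmsd near the generator sigma
  cfg <- simulation_config(n_models = 60, seed = 9)
  noisy <- generate_corpus_memory(cfg)
  rep2 <- corpus_report(noisy, rhomboid_restraints(), bin_width = 1)
  expect_equal(sum(rep2$n), 60L)
  pooled <- sqrt(sum(rep2$n * rep2$bond_rmsd^2) / sum(rep2$n))
  expect_equal(pooled, 0.024, tolerance = 0.35)

  # missing resolution: skipped with a warning
  corpus$resolution[1] <- NA
  expect_warning(rep3 <- corpus_report(corpus, rhomboid_restraints()),
                 "resolution")
  expect_equal(sum(rep3$n), 9L)
})

test_that("autoplot returns a ggplot for a corpus report", {
  cfg <- simulation_config(n_models = 10, seed = 3)
  rep <- corpus_report(generate_corpus_memory(cfg), rhomboid_restraints())
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("validate_model reports rmsd, links and class per cluster", {
  model <- template_with_cys()
  out <- validate_model(model)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_links, 4L)
  expect_equal(out$classification, "rhomboid")
  expect_lt(out$bond_rmsd, 0.005)
})
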