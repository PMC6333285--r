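meta_row <- function(entry_id = "E1", resolution = 2.0, r_work = 0.20,
                     r_free = 0.25, completeness = 0.95, twinned = FALSE,
                     has_structure_factors = TRUE, r_factor = 0.04) {
  tibble::tibble(entry_id = entry_id, resolution = resolution,
                 r_work = r_work, r_free = r_free,
                 completeness = completeness, twinned = twinned,
                 has_structure_factors = has_structure_factors,
                 r_factor = r_factor)
}

test_that("small-molecule R-factor filter is inclusive at the cutoff", {
  entries <- dplyr::bind_rows(
    meta_row("A", r_factor = 0.05),
    meta_row("B", r_factor = 0.06),
    meta_row("C", r_factor = 0.049))
  kept <- filter_small_molecule(entries, search_mode("S", 0.05))
  expect_setequal(kept$entry_id, c("A", "C"))
  kept2 <- filter_small_molecule(entries, search_mode("X", 0.1))
  expect_setequal(kept2$entry_id, c("A", "B", "C"))
  expect_equal(nrow(filter_small_molecule(entries[0, ])), 0L)
  # CSD-style boolean columns are honoured when present
  entries$has_3d <- c(TRUE, TRUE, FALSE)
  expect_setequal(filter_small_molecule(entries)$entry_id, "A")
})

test_that("refinement filter reproduces every threshold rule", {
  entries <- dplyr::bind_rows(
    meta_row("ok"),
    meta_row("res_at_limit", resolution = 3.55),
    meta_row("res_worse", resolution = 3.56),
    meta_row("no_sf", has_structure_factors = FALSE),
    meta_row("twin", twinned = TRUE),
    meta_row("incomplete", completeness = 0.899),
    meta_row("complete_at_limit", completeness = 0.90),
    meta_row("rwork_high", r_work = 0.30, r_free = 0.34),
    meta_row("rwork_edge", r_work = 0.299, r_free = 0.34),
    meta_row("rfree_high", r_free = 0.35),
    meta_row("gap_small", r_work = 0.25, r_free = 0.264),
    meta_row("gap_at_limit", r_work = 0.25, r_free = 0.265),
    meta_row("missing_res", resolution = NA))
  kept <- filter_refinement_entries(entries)
  expect_setequal(kept$entry_id,
                  c("ok", "res_at_limit", "complete_at_limit",
                    "rwork_edge", "gap_at_limit"))
  dropped <- attr(kept, "dropped")
  expect_equal(dropped$reason[dropped$entry_id == "res_worse"],
               "resolution worse than 3.55 A")
  expect_equal(dropped$reason[dropped$entry_id == "gap_small"],
               "R_free - R_work below 1.5%")
  expect_equal(dropped$reason[dropped$entry_id == "missing_res"],
               "missing resolution")

  # oracle: direct rule evaluation on the same table
  direct <- with(entries,
                 !is.na(resolution) & resolution <= 3.55 &
                   has_structure_factors & !twinned &
                   completeness >= 0.90 & r_work < 0.30 & r_free < 0.35 &
                   (r_free - r_work) >= 0.015)
  expect_setequal(kept$entry_id, entries$entry_id[direct])
})

test_that("high-resolution filter is strict at 1 Angstrom", {
  entries <- dplyr::bind_rows(
    meta_row("keep", resolution = 0.95),
    meta_row("at_limit", resolution = 1.00),
    meta_row("no_sf", resolution = 0.9, has_structure_factors = FALSE))
  expect_equal(filter_high_res(entries)$entry_id, "keep")
  entries$cluster_complete <- c(FALSE, TRUE, TRUE)
  expect_equal(nrow(filter_high_res(entries)), 0L)
})

test_that("filters are idempotent and order-independent", {
  set.seed(31)
  entries <- meta_row(sprintf("E%03d", 1:50),
                      resolution = runif(50, 0.8, 4),
                      r_work = runif(50, 0.15, 0.35),
                      r_free = runif(50, 0.18, 0.40),
                      completeness = runif(50, 0.8, 1),
                      twinned = runif(50) < 0.1,
                      r_factor = runif(50, 0.02, 0.12))
  f1 <- filter_refinement_entries(entries)
  expect_equal(filter_refinement_entries(f1)$entry_id, f1$entry_id)
  a <- filter_small_molecule(filter_refinement_entries(entries))
  b <- filter_refinement_entries(filter_small_molecule(entries))
  expect_equal(a$entry_id, b$entry_id)
})

test_that("aggregation pools per measurement with sample sd", {
  p1 <- cluster_profile(build_rhomboid())
  st <- aggregate_geometry(list(p1))
  expect_equal(st$mean[st$class == "S-Fe"], 2.289, tolerance = 0.005)
  expect_equal(st$sd[st$class == "S-Fe"], 0, tolerance = 1e-9)
  expect_equal(st$n[st$class == "S-Fe"], 12L)

  # two uniform-bond profiles at 2.0 and 2.2 pool to mean 2.1
  t1 <- build_cubic(2.0)
  t2 <- build_cubic(2.2)
  st2 <- aggregate_geometry(list(cluster_profile(t1), cluster_profile(t2)))
  expect_equal(st2$mean[st2$class == "S-Fe"], 2.1)
  expect_equal(st2$n[st2$class == "S-Fe"], 24L)
  # sample sd over the 24 pooled bonds
  expect_equal(st2$sd[st2$class == "S-Fe"],
               sd(rep(c(2.0, 2.2), each = 12)))

  expect_error(aggregate_geometry(list()), "empty")
})

test_that("pooled moments merge across corpus halves", {
  cfg <- simulation_config(n_models = 40, seed = 17)
  profs <- lapply(1:40, function(i) {
    g <- generate_cluster_model(cfg, i)
    cluster_profile(find_clusters(g$model)[[1]])
  })
  whole <- aggregate_geometry(profs)
  a <- aggregate_geometry(profs[1:15])
  b <- aggregate_geometry(profs[16:40])
  for (cl in c("S-Fe", "Fe-S-Fe", "S-Fe-S")) {
    na <- a$n[a$class == cl]
    nb <- b$n[b$class == cl]
    ma <- a$mean[a$class == cl]
    mb <- b$mean[b$class == cl]
    pooled_mean <- (na * ma + nb * mb) / (na + nb)
    pooled_ss <- (na - 1) * a$sd[a$class == cl]^2 +
      (nb - 1) * b$sd[b$class == cl]^2 +
      na * nb / (na + nb) * (ma - mb)^2
    pooled_sd <- sqrt(pooled_ss / (na + nb - 1))
    expect_equal(whole$mean[whole$class == cl], pooled_mean,
                 tolerance = 1e-9)
    expect_equal(whole$sd[whole$class == cl], pooled_sd, tolerance = 1e-9)
  }
})

test_that("mining a generated corpus recovers the generator parameters", {
  n <- 200
  cfg <- simulation_config(n_models = n, seed = 23, with_cysteines = TRUE)
  corpus <- generate_corpus_memory(cfg)
  st <- mine_corpus(corpus, mode = search_mode("S"))
  # 3 sigma / sqrt(N) recovery bands on the means
  expect_lt(abs(st$mean[st$class == "S-Fe"] - 2.289),
            3 * 0.024 / sqrt(12 * n))
  # angle draws are projected onto the feasible shape family during the
  # rebuild, which adds a small (< 0.1 deg) deterministic bias on top of
  # the sampling band
  expect_lt(abs(st$mean[st$class == "Fe-S-Fe"] - 73.66),
            3 * 0.87 / sqrt(12 * n) + 0.1)
  expect_lt(abs(st$mean[st$class == "Fe-S_AA"] - 2.268),
            3 * 0.017 / sqrt(4 * n))
  # the bond is reproduced exactly by the rebuild, so its sigma is too
  expect_equal(st$sd[st$class == "S-Fe"], 0.024, tolerance = 0.15)

  # S mode drops non-cysteine link partners
  prof <- cluster_profile(find_clusters(corpus$model[[1]])[[1]],
                          links = detect_links(
                            find_clusters(corpus$model[[1]])[[1]],
                            corpus$model[[1]]))
  prof$partner_residue[prof$class == "Fe-S_AA"] <- "MET"
  st_s <- aggregate_geometry(list(prof), mode = search_mode("S"))
  expect_false("Fe-S_AA" %in% st_s$class)
  st_x <- aggregate_geometry(list(prof), mode = search_mode("X"))
  expect_true("Fe-S_AA" %in% st_x$class)
})

test_that("a mined near-ideal cubic corpus yields a cubic dictionary", {
  # small Cartesian jitter keeps the sample sigmas positive (a degenerate
  # zero-sigma class is rejected by restraints_from_stats)
  cfg <- simulation_config(n_models = 5, seed = 3, geometry = "cubic",
                           bond_sigma = 0.005, coord_noise = 0.003)
  corpus <- generate_corpus_memory(cfg)
  st <- mine_corpus(corpus)
  set <- restraints_from_stats(st)
  expect_equal(set$label, "cubic")
  expect_equal(set$bonds$value[1], 2.135, tolerance = 0.005)
  expect_equal(unique(set$angles$value), c(90, 90), tolerance = 0.01)
})
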