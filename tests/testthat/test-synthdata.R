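test_that("simulated trees are ultrametric with the requested depth and tip count", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(max(ape::node.depth.edgelength(tr2)), 60, tolerance = 1e-9)
  tr <- simulate_tree(42, seed = 2)
  expect_equal(length(tr$tip.label), 42L)
  depths <- ape::node.depth.edgelength(tr)[1:42]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(simulate_tree(5, birth = 0.1, death = 0.2), "birth")
})

test_that("clade assignment gives the requested number of groups of adequate size", {
  for (s in 1:10) {
    tr <- simulate_tree(41, seed = s)
    cl <- assign_clades(tr, 3, min_size = 3)
    expect_setequal(unique(cl), c("clade1", "clade2", "clade3"))
    expect_true(all(table(cl) >= 3))
    expect_identical(names(cl), tr$tip.label)
  }
})

test_that("datasets are reproducible from (config, seed) and ground truth is complete", {
  cfg <- scenario_config(seed = 9)
  d1 <- simulate_jaw_dataset(cfg)
  d2 <- simulate_jaw_dataset(cfg)
  expect_identical(d1$traits, d2$traits)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$ranges, d2$ranges)
  expect_identical(write_tps(d1$outlines, tempfile()) |> readLines(),
                   write_tps(d2$outlines, tempfile()) |> readLines())
  expect_true(all(c("clades", "lambda_true", "unknown_clade", "seed") %in%
                    names(d1$truth)))
  expect_identical(nrow(d1$traits), 42L)
  expect_identical(d1$labels$role[d1$labels$taxon_id == "unknown"], "unknown")
})

test_that("zero deviation and zero noise reproduce the template exactly", {
  cfg <- scenario_config(noise_sd = 0, seed = 1)
  base <- base_jaw_template(25, 300)
  dev <- matrix(0, 2, 100, dimnames = list(c("u", "v"), names(coeffs_to_vector(base))))
  outs <- traits_to_outlines(base, dev, cfg)
  ref <- inverse_efa(base, 300)
  expect_lt(max(abs(outs$outlines$u$points - ref$points)), 1e-9)
  expect_lt(max(abs(outs$outlines$v$points - ref$points)), 1e-9)
})

test_that("generated outlines round-trip their coefficients through EFA", {
  # moderate-deviation regime: tracing deviated coefficients and
  # re-decomposing is close to the identity (the arc-length
  # re-parametrization it involves is near-linear there)
  ds <- simulate_jaw_dataset(scenario_config(seed = 3, clade_effect_size = 0.05))
  dec <- efa_decompose_set(prepare_outlines(ds$outlines, 300), 25)
  base_v <- coeffs_to_vector(base_jaw_template())
  lo <- 1:24   # a1..d6, the coefficients carrying variance
  pt <- vapply(rownames(ds$traits), function(id) {
    stats::cor((base_v + ds$traits[id, ])[lo], coeffs_to_vector(dec[[id]])[lo])
  }, numeric(1))
  expect_gt(stats::median(pt), 0.99)
  expect_gt(min(pt), 0.97)
  # at full default clade offsets the map is still faithful for the
  # thickness coefficient that defines the leading axis
  ds2 <- simulate_jaw_dataset(scenario_config(seed = 3))
  dec2 <- efa_decompose_set(prepare_outlines(ds2$outlines, 300), 25)
  X2 <- efa_matrix(dec2)
  input_d1 <- base_v["d1"] + ds2$traits[rownames(X2), "d1"]
  expect_gt(stats::cor(input_d1, X2[, "d1"]), 0.99)
})

test_that("trait simulation carries the configured phylogenetic signal", {
  set.seed(40)
  tr <- simulate_tree(64, seed = 41)
  C <- phylo_vcv(tr)
  lam_hat <- function(lt, reps = 30) {
    cfg <- scenario_config(lambda_true = lt, clade_effect_size = 0, seed = 1)
    vapply(seq_len(reps), function(i) {
      M <- simulate_shape_traits(tr, cfg)
      pagel_lambda(tr, M[, "d1"], C = C)$lambda
    }, numeric(1))
  }
  expect_gte(median(lam_hat(1)), 0.9)
  expect_lte(median(lam_hat(0)), 0.1)
})

test_that("convergence pairs pull cross-clade taxa together", {
  tr <- simulate_tree(30, seed = 50)
  cl <- assign_clades(tr, 3)
  pairs <- auto_convergence_pairs(cl, 0.2)
  expect_true(all(vapply(pairs, function(p) cl[p[1]] != cl[p[2]], logical(1))))
  set.seed(51)
  cfg <- scenario_config(n_taxa = 30, convergence_pairs = pairs, seed = 51)
  M <- simulate_shape_traits(tr, cfg, cl)
  D <- as.matrix(dist(M))
  for (p in pairs) {
    others <- setdiff(rownames(M)[cl[rownames(M)] == cl[p[2]]], p)
    expect_lt(D[p[1], p[2]], min(D[p[1], others]))
  }
})

test_that("degraded topologies have the requested polytomies and valid ranges", {
  tr <- simulate_tree(30, seed = 60)
  deg0 <- degrade_topology(tr, polytomy_fraction = 0, range_width_myr = 0)
  expect_true(ape::is.binary(deg0$topology))
  expect_true(all(deg0$ranges$age_max_ma == deg0$ranges$age_min_ma))
  deg <- degrade_topology(tr, polytomy_fraction = 0.5, range_width_myr = 10,
                          seed = 61)
  expect_lt(deg$topology$Nnode, tr$Nnode)
  expect_true(all(deg$ranges$age_max_ma - deg$ranges$age_min_ma <= 10 + 1e-9))
  expect_true(all(deg$ranges$age_min_ma >= 0))
  # resolved trees differ across seeds
  k1 <- ape::write.tree(resolve_polytomies(deg$topology, seed = 1))
  k2 <- ape::write.tree(resolve_polytomies(deg$topology, seed = 2))
  expect_false(identical(k1, k2))
})

test_that("ensemble K on degraded inputs recovers the true-tree K without bias", {
  # per-dataset deviation has SD ~0.2 under the default degradation
  # (half the nodes collapsed, 10-Myr ranges); the recovery property is
  # that the ensemble estimator is unbiased for Brownian shape data
  diffs <- vapply(70:75, function(s) {
    ds <- simulate_jaw_dataset(scenario_config(seed = s, clade_effect_size = 0),
                               outlines = FALSE)
    comp <- setdiff(rownames(ds$traits), "unknown")
    x <- ds$traits[comp, "d1"]
    D <- as.matrix(dist(ds$traits[comp, ]))
    es <- ensemble_signal(ds$topology, ds$ranges, x, D, n_trees = 25,
                          n_perm = 5, master_seed = s + 1)
    es$summary$mean[es$summary$statistic == "K"] - blomberg_k(ds$tree, x)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.15)
})
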