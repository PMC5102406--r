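test_that("generated DAGs are acyclic, reproducible, and density-calibrated", {
  cfg <- sim_config(n_nodes = 10, n_samples = 20, seed = 42)
  g1 <- generate_dag(cfg)
  g2 <- generate_dag(cfg)
  expect_identical(g1, g2)
  ig <- igraph::graph_from_data_frame(g1$edges[c("parent", "child")],
                                      vertices = g1$nodes)
  expect_true(igraph::is_dag(ig))

  # expected edge count 0.1 * choose(20, 2) = 19 over replicate draws
  counts <- vapply(1:200, function(s)
    nrow(generate_dag(sim_config(n_nodes = 20, edge_density = 0.1,
                                 seed = s))$edges), 0L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 19), 3 * se)
})

test_that("degenerate generator configs are rejected", {
  expect_error(sim_config(n_nodes = 0), "invalid config")
  expect_error(sim_config(edge_density = 0), "invalid config")
  expect_error(sim_config(censor_fraction = 1.5), "invalid config")
})

test_that("single node yields an empty graph", {
  g <- generate_dag(sim_config(n_nodes = 1, edge_density = 0.5))
  expect_equal(nrow(g$edges), 0L)
})

test_that("noiseless local models are exact linear functions of parents", {
  net <- ground_truth_network(
    nodes = c("A", "B"),
    edges = data.frame(parent = "A", child = "B", effect = 2,
                       class = "plain", modulator = NA, active_level = NA,
                       effect_alt = NA),
    noise_scale = c(1, 0))   # A noisy, B noiseless
  cfg <- sim_config(n_nodes = 2, n_samples = 50, censor_fraction = 0)
  sim <- simulate_samples(net, cfg)
  x <- sim$data$continuous
  expect_equal(x[, "B"], 2 * x[, "A"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("switched-conditional effects vanish when the modulator is inactive", {
  net <- ground_truth_network(
    nodes = c("A", "B"),
    edges = data.frame(parent = "A", child = "B", effect = 2,
                       class = "switched", modulator = "sw",
                       active_level = "1", effect_alt = NA),
    modulators = list(sw = c("0", "1")),
    noise_scale = 1)
  cfg <- sim_config(n_nodes = 2, n_samples = 500, censor_fraction = 0,
                    seed = 9)
  sim <- simulate_samples(net, cfg)
  inactive <- sim$modulators$sw == "0"
  r0 <- cor(sim$data$continuous[inactive, "A"],
            sim$data$continuous[inactive, "B"])
  # null correlation at n ~ 250: |r| under 3/sqrt(n)
  expect_lt(abs(r0), 3 / sqrt(sum(inactive)))
  active <- !inactive
  r1 <- cor(sim$data$continuous[active, "A"],
            sim$data$continuous[active, "B"])
  expect_gt(r1, 0.5)
})

test_that("censoring respects censor_fraction and pairs switches", {
  cfg <- sim_config(n_nodes = 10, n_samples = 40, censor_fraction = 0,
                    seed = 3)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  expect_false(any(grepl("_cens$", names(sim$data$discrete))))

  cfg2 <- sim_config(n_nodes = 10, n_samples = 40, censor_fraction = 0.25,
                     metabolite_fraction = 0.3, seed = 3)
  sim2 <- simulate_samples(generate_dag(cfg2), cfg2)
  mets <- names(sim2$data$roles)[sim2$data$roles == "metabolite"]
  for (v in mets) {
    sw <- sim2$data$discrete[[paste0(v, "_cens")]]
    expect_false(is.null(sw))
    expect_equal(mean(sw == "0"), 0.25, tolerance = 0.05)
    # censored entries sit exactly at the detection limit
    expect_equal(unname(min(sim2$data$continuous[, v])),
                 unname(sim2$detection_limits[v]))
  }
})

test_that("cyclic ground truth is rejected at simulation time", {
  net <- ground_truth_network(c("A", "B"),
                              data.frame(parent = "A", child = "B",
                                         effect = 1))
  net$edges <- rbind(net$edges,
                     data.frame(parent = "B", child = "A", effect = 1,
                                class = "plain", modulator = NA,
                                active_level = NA, effect_alt = NA))
  expect_error(simulate_samples(net, sim_config(n_nodes = 2)), "acyclic")
})

test_that("probe emission reproduces latent values exactly at zero noise", {
  cfg <- sim_config(n_nodes = 4, n_samples = 12, probes_per_node = 1,
                    n_lineages = 1, probe_noise = 0, spot_noise = 0,
                    censor_fraction = 0, seed = 5)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  pro <- emit_probe_level(sim$data, cfg)
  pm <- aggregate_spots(pro$spots, pro$annotation)
  recovered <- t(log(pm$values))[rownames(sim$data$continuous), ]
  colnames(recovered) <- sub("_p01$", "", colnames(recovered))
  expect_equal(recovered[, colnames(sim$data$continuous)],
               sim$data$continuous, tolerance = 1e-10)
})

test_that("probe redundancy separates lineages and replicates spots", {
  cfg <- sim_config(n_nodes = 8, n_samples = 100, probes_per_node = 4,
                    n_lineages = 2, censor_fraction = 0, seed = 11)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  pro <- emit_probe_level(sim$data, cfg)

  # every probe replicated >= 4 spots
  spot_counts <- table(pro$spots$probe, pro$spots$sample)
  expect_true(all(spot_counts >= 4))

  # within-lineage correlation beats between-lineage in >= 95% of bins
  pm <- aggregate_spots(pro$spots, pro$annotation)
  ok <- vapply(unique(pro$annotation$bin), function(b) {
    ann <- pro$annotation[pro$annotation$bin == b, ]
    cc <- cor(t(log(pm$values[ann$probe, ])))
    same <- outer(ann$lineage, ann$lineage, `==`) & upper.tri(cc)
    diff <- !outer(ann$lineage, ann$lineage, `==`) & upper.tri(cc)
    mean(cc[same]) > mean(cc[diff])
  }, TRUE)
  expect_gte(mean(ok), 0.95)

  # identity annotation straddles the 85% cutoff
  idm <- as.matrix(pro$annotation[grep("identity", names(pro$annotation))])
  target <- idm[cbind(seq_len(nrow(idm)), pro$annotation$lineage)]
  expect_true(all(target >= 95))
  expect_true(all(idm[idm < 95] <= 80))
})

test_that("ground truth round-trips to GraphML with a JSON sidecar", {
  skip_if_not_installed("jsonlite")
  cfg <- sim_config(n_nodes = 6, fraction_conditional = 0.5,
                    edge_density = 0.4, seed = 8)
  gt <- generate_dag(cfg)
  gml <- tempfile(fileext = ".graphml"); js <- tempfile(fileext = ".json")
  write_ground_truth(gt, gml, js)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, gt$nodes)
  expect_equal(igraph::ecount(g), nrow(gt$edges))
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(side$edges), nrow(gt$edges))
  expect_setequal(names(side$modulators), names(gt$modulators))
})
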