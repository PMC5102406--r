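test_that("spot aggregation is the geometric mean and is order-invariant", {
  spots <- data.frame(probe = "p1", sample = "s1", intensity = c(4, 16),
                      bg_mean = c(0.1, 0.2), bg_sd = c(0.01, 0.02))
  expect_equal(unname(aggregate_spots(spots)$values["p1", "s1"]), 8)

  one <- data.frame(probe = "p1", sample = "s1", intensity = 5)
  expect_equal(unname(aggregate_spots(one)$values["p1", "s1"]), 5)

  eight <- data.frame(probe = "p1", sample = "s1",
                      intensity = c(1, 1, 1, 1, 1, 1, 1, 8))
  expect_equal(unname(aggregate_spots(eight)$values["p1", "s1"]), 8^(1 / 8),
               tolerance = 1e-12)

  fx <- spot_fixture(n_probes = 6, seed = 2)
  perm <- fx$spots[sample(nrow(fx$spots)), ]
  expect_equal(aggregate_spots(fx$spots)$values,
               aggregate_spots(perm)$values)

  bad <- data.frame(probe = c("p1", "p2"), sample = "s1",
                    intensity = c(3, -1))
  expect_error(aggregate_spots(bad), "p2")
})

test_that("background filter retains exactly the probes above mean + k sd", {
  vals <- rbind(bright = c(0.05, 0.16, 0.05),   # one sample above 0.14
                dim    = c(0.13, 0.14, 0.12))   # never above
  colnames(vals) <- paste0("s", 1:3)
  bg_m <- matrix(0.1, 2, 3, dimnames = dimnames(vals))
  bg_s <- matrix(0.02, 2, 3, dimnames = dimnames(vals))
  m <- probe_matrix(vals, bg_mean = bg_m, bg_sd = bg_s)
  out <- filter_background(m, k = 2)
  expect_identical(rownames(out$values), "bright")
  expect_identical(attr(out, "removed"), "dim")
  expect_error(filter_background(m, k = -1), "invalid parameter")

  # planted dark probes equal the removed set, against the brute-force rule
  fx <- spot_fixture(n_probes = 30, dark_fraction = 0.3, seed = 7)
  pm <- aggregate_spots(fx$spots)
  filtered <- filter_background(pm, k = 2)
  brute <- rownames(pm$values)[
    !apply(pm$values > pm$bg_mean + 2 * pm$bg_sd, 1, any)]
  expect_identical(sort(attr(filtered, "removed")), sort(brute))
  expect_identical(sort(attr(filtered, "removed")), fx$dark)
})

test_that("ortholog collapse keeps the brightest probe per correlated group", {
  m <- collapse_fixture()
  out <- collapse_orthologs(m, r_min = 0.9)

  # binA: three probes, two correlated -> brighter of the pair + distinct
  binA <- out$matrix$annotation$probe[out$matrix$annotation$bin == "binA"]
  expect_setequal(binA, c("a2", "a3"))

  # binB: six probes in two lineage clusters -> two representatives
  binB <- out$matrix$annotation$probe[out$matrix$annotation$bin == "binB"]
  expect_setequal(binB, c("b2", "b5"))

  # representatives match the independent brute-force implementation
  expect_identical(sort(rownames(out$matrix$values)), brute_collapse(m))

  # conservation: every input probe appears exactly once in the report
  expect_setequal(out$report$probe, rownames(m$values))
  expect_false(anyDuplicated(out$report$probe) > 0)

  # idempotence
  again <- collapse_orthologs(out$matrix, r_min = 0.9)
  expect_identical(again$matrix$values, out$matrix$values)

  # exact duplicate column collapses (r = 1)
  dup <- probe_matrix(rbind(p1 = m$values["a1", ], p2 = m$values["a1", ]),
                      data.frame(probe = c("p1", "p2"), bin = "b"))
  expect_equal(nrow(collapse_orthologs(dup)$matrix$values), 1L)

  expect_error(collapse_orthologs(probe_matrix(m$values[, 1:2])),
               "3 samples")
})

test_that("filter + collapse retained count matches a brute-force recount", {
  fx <- spot_fixture(n_probes = 24, n_samples = 12, dark_fraction = 0.25,
                     seed = 9)
  pm <- aggregate_spots(fx$spots)
  pm$annotation$bin <- rep(sprintf("bin%d", 1:6), each = 4)
  filtered <- filter_background(pm, k = 2)
  collapsed <- collapse_orthologs(filtered, r_min = 0.9)

  bright <- rownames(pm$values)[
    apply(pm$values > pm$bg_mean + 2 * pm$bg_sd, 1, any)]
  sub <- probe_matrix(pm$values[bright, , drop = FALSE],
                      pm$annotation[pm$annotation$probe %in% bright, ])
  expect_identical(sort(rownames(collapsed$matrix$values)),
                   brute_collapse(sub))
})

test_that("censoring substitutes limits, sets switches, and transforms", {
  vals <- cbind(met = c(0, 256, 0.5), rate = c(1, 2, 3))
  out <- censor_and_transform(vals, detection_limits = NULL,
                              censorable = "met")
  # zero with no detection limit -> 1e-4 stored as (1e-4)^(1/8)
  expect_equal(unname(out$continuous[1, "met"]), 10^(-4 / 8),
               tolerance = 1e-12)
  expect_equal(unname(out$continuous[2, "met"]), 2)   # 256^(1/8)
  expect_identical(as.character(out$discrete$met_cens), c("0", "1", "1"))

  # value at the detection limit is censored (boundary convention)
  out2 <- censor_and_transform(cbind(met = c(4, 5)),
                               detection_limits = c(met = 4))
  expect_identical(as.character(out2$discrete$met_cens), c("0", "1"))
  expect_equal(unname(out2$continuous[1, "met"]), 4^(1 / 8))

  expect_error(censor_and_transform(cbind(met = -1)), "negative")
  expect_error(censor_and_transform(cbind(a = c(0, 1))), "censorable")
})

test_that("the eighth-root transform preserves rankings", {
  set.seed(1)
  vals <- cbind(v = rexp(50) + 1e-6)
  out <- censor_and_transform(vals)
  expect_identical(order(out$continuous[, "v"]), order(vals[, "v"]))
})

test_that("variable tables round-trip through TSV", {
  cfg <- sim_config(n_nodes = 5, n_samples = 10, censor_fraction = 0.2,
                    metabolite_fraction = 0.4, fraction_conditional = 0.5,
                    edge_density = 0.4, seed = 6)
  sim <- simulate_samples(generate_dag(cfg), cfg)
  path <- tempfile(fileext = ".tsv")
  write_variable_table(sim$data, path)
  back <- read_variable_table(path)
  expect_equal(back$continuous, sim$data$continuous, tolerance = 1e-9)
  expect_identical(back$roles, sim$data$roles)
  expect_identical(lapply(back$discrete, as.character),
                   lapply(sim$data$discrete, as.character))
})

test_that("GEO series-matrix text parses into a probe matrix", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"demo\"",
               "!series_matrix_table_begin",
               "ID_REF\tGSM1\tGSM2",
               "probeA\t1.5\t2.5",
               "probeB\t0.5\t0.25",
               "!series_matrix_table_end"), path)
  m <- read_series_matrix(path)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(unname(m$values["probeB", "GSM2"]), 0.25)
  plain <- tempfile()
  writeLines("just text", plain)
  expect_error(read_series_matrix(plain), "series-matrix")
})
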