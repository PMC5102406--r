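## Synthetic-data module: ground-truth networks, linear-Gaussian samples with
## conditional edges and censoring, and probe/spot-level emission with
## multi-lineage redundancy.  Everything is driven by a sim_config whose seed
## fully determines the output.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults emulate the
#' scale of the mixed-culture microarray studies the pipeline is designed
#' for: a sparse 20-node regulatory layer observed across ~48 cDNA pools,
#' with a minority of condition-modulated edges, a small fraction of
#' below-detection metabolite measurements, and redundant probes split over
#' two strain lineages, each spotted at least four times.
#'
#' @param n_nodes number of latent continuous variables (>= 1).
#' @param n_samples number of samples (cDNA pools).
#' @param edge_density probability that an ordered node pair carries an edge;
#'   expected edge count is `edge_density * n_nodes * (n_nodes - 1) / 2`.
#' @param fraction_conditional fraction of edges carrying a discrete
#'   modulator (split between switched- and linearly-conditional).
#' @param probes_per_node probes spawned per latent variable (>= 1).
#' @param n_lineages strain lineages the probes are split across.
#' @param background_mean,background_sd background fluorescence statistics
#'   recorded per spot, on the intensity-ratio scale.
#' @param censor_fraction fraction of each metabolite variable's values
#'   pushed below detection.
#' @param seed integer seed; identical configs give bit-identical output.
#' @param metabolite_fraction fraction of nodes designated metabolite-like
#'   (the only censorable variables).
#' @param noise_scale local-model Gaussian noise SD, applied to every node.
#' @param modulator_levels 2 for binary modulators; >= 3 makes
#'   linearly-conditional edges use a tiered (multi-level) modulator, as with
#'   an electron-acceptor type partitioning the dataset.
#' @param probe_noise,spot_noise SD of probe-specific and spot-replicate
#'   noise (log-intensity scale).
#' @param n_spots replicate spots per probe (>= 4 on the emulated platform).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_nodes = 20, n_samples = 48, edge_density = 0.1,
                       fraction_conditional = 0.1, probes_per_node = 2,
                       n_lineages = 2, background_mean = 0.1,
                       background_sd = 0.02, censor_fraction = 0.1,
                       seed = 1L, metabolite_fraction = 0.2,
                       noise_scale = 1, modulator_levels = 2,
                       probe_noise = 0.1, spot_noise = 0.05, n_spots = 4) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_samples = as.integer(n_samples),
              edge_density = edge_density,
              fraction_conditional = fraction_conditional,
              probes_per_node = as.integer(probes_per_node),
              n_lineages = as.integer(n_lineages),
              background_mean = background_mean,
              background_sd = background_sd,
              censor_fraction = censor_fraction, seed = as.integer(seed),
              metabolite_fraction = metabolite_fraction,
              noise_scale = noise_scale,
              modulator_levels = as.integer(modulator_levels),
              probe_noise = probe_noise, spot_noise = spot_noise,
              n_spots = as.integer(n_spots))
  with(cfg, {
    if (n_nodes < 1L || n_samples < 1L || probes_per_node < 1L ||
        n_lineages < 1L || n_spots < 1L)
      stop("invalid config: all counts must be positive")
    if (edge_density <= 0 || edge_density >= 1)
      stop("invalid config: edge_density must lie in (0, 1)")
    if (fraction_conditional < 0 || fraction_conditional > 1 ||
        censor_fraction < 0 || censor_fraction > 1)
      stop("invalid config: fractions must lie in [0, 1]")
    if (background_mean <= 0 || background_sd < 0 || noise_scale < 0)
      stop("invalid config: background/noise scales must be nonnegative")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a ground-truth network by hand
#'
#' @param nodes character vector of variable ids.
#' @param edges data.frame with columns `parent`, `child`, `effect`
#'   (nonzero slope at the modulator's active level), `class` (one of
#'   `"plain"`, `"switched"`, `"linear"`), `modulator` (discrete variable id,
#'   `NA` for plain), `active_level`, and `effect_alt` (slope at non-active
#'   levels of a linearly-conditional edge; ignored otherwise).
#' @param modulators named list: modulator id -> character vector of levels.
#' @param noise_scale per-node Gaussian noise SD (recycled).
#' @param roles named character of node roles (see [variable_table()]).
#' @return object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(nodes, edges, modulators = list(),
                                 noise_scale = 1, roles = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("parent", "child", "effect", "class", "modulator",
            "active_level", "effect_alt")
  for (col in setdiff(need, names(edges)))
    edges[[col]] <- if (col %in% c("modulator", "active_level")) NA_character_
                    else if (col == "class") "plain" else NA_real_
  edges <- edges[need]
  if (nrow(edges)) {
    if (any(!edges$class %in% c("plain", "switched", "linear")))
      stop("unknown edge class")
    if (any(!is.finite(edges$effect) | edges$effect == 0))
      stop("effect sizes must be finite and nonzero")
    cond <- edges$class != "plain"
    if (any(cond & (is.na(edges$modulator) |
                    !edges$modulator %in% names(modulators))))
      stop("every conditional edge must reference a declared modulator")
    if (!all(c(edges$parent, edges$child) %in% nodes))
      stop("edge endpoints must be declared nodes")
  }
  if (!is_acyclic(nodes, edges))
    stop("ground-truth network must be acyclic")
  if (is.null(roles)) roles <- setNames(rep("transcript", length(nodes)), nodes)
  structure(list(nodes = nodes, edges = edges, modulators = modulators,
                 noise_scale = setNames(rep_len(noise_scale, length(nodes)),
                                        nodes),
                 roles = roles[nodes]),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("ground_truth_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$class != "plain"), "conditional ),",
      length(x$modulators), "modulators\n")
  invisible(x)
}

#' Generate a random ground-truth DAG
#'
#' Draws a random topological order, then includes each ordered pair as an
#' edge with probability `edge_density`, so the expected edge count is
#' `edge_density * choose(n_nodes, 2)`.  Effect sizes are drawn uniformly
#' from +/-[0.5, 1.5]; a `fraction_conditional` of edges receive a discrete
#' modulator and are switched- or linearly-conditional with equal
#' probability.  A `metabolite_fraction` of nodes is designated
#' metabolite-like (censorable downstream).
#'
#' @param config a [sim_config()].
#' @return a `ground_truth_network`.
#' @export
generate_dag <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_nodes < 1L) stop("invalid config: n_nodes must be >= 1")
  with_seed(config$seed, {
    n <- config$n_nodes
    nodes <- sprintf("v%02d", seq_len(n))
    ord <- sample(nodes)
    pairs <- if (n >= 2L) t(combn(n, 2L)) else matrix(integer(0), 0, 2)
    keep <- runif(nrow(pairs)) < config$edge_density
    edges <- data.frame(parent = ord[pairs[keep, 1L]],
                        child = ord[pairs[keep, 2L]],
                        stringsAsFactors = FALSE)
    m <- nrow(edges)
    edges$effect <- sample(c(-1, 1), m, TRUE) * runif(m, 0.5, 1.5)
    edges$class <- rep("plain", m)
    edges$modulator <- rep(NA_character_, m)
    edges$active_level <- rep(NA_character_, m)
    edges$effect_alt <- rep(NA_real_, m)
    modulators <- list()
    n_cond <- round(config$fraction_conditional * m)
    if (n_cond > 0) {
      idx <- sample(m, n_cond)
      cls <- sample(c("switched", "linear"), n_cond, TRUE)
      n_mod <- max(1L, ceiling(n_cond / 3))
      # switched-conditional modulators must be binary; tiered levels (if
      # configured) are reserved for linearly-conditional edges
      mod_names <- sprintf("mod%02d", seq_len(n_mod))
      lv_binary <- c("0", "1")
      lv_tier <- as.character(seq_len(config$modulator_levels) - 1L)
      for (k in seq_len(n_mod)) modulators[[mod_names[k]]] <- lv_binary
      if (config$modulator_levels > 2L && any(cls == "linear")) {
        modulators[["tier01"]] <- lv_tier
      }
      assigned <- sample(mod_names, n_cond, TRUE)
      assigned[cls == "linear" & config$modulator_levels > 2L] <- "tier01"
      edges$class[idx] <- cls
      edges$modulator[idx] <- assigned
      edges$active_level[idx] <-
        vapply(modulators[assigned], function(lv) lv[[length(lv)]], "")
      alt <- sample(c(-1, 1), n_cond, TRUE) * runif(n_cond, 0, 0.3)
      edges$effect_alt[idx] <- ifelse(cls == "linear", alt, NA_real_)
    }
    n_met <- round(config$metabolite_fraction * n)
    roles <- setNames(rep("transcript", n), nodes)
    if (n_met > 0) roles[sample(nodes, n_met)] <- "metabolite"
    ground_truth_network(nodes, edges, modulators,
                         noise_scale = config$noise_scale, roles = roles)
  })
}

#' Simulate samples from a ground-truth network
#'
#' Discrete modulators are assigned balanced levels across samples, then
#' continuous values are generated in topological order from the local
#' linear-Gaussian models.  Switched-conditional effects contribute only in
#' samples where the modulator sits at its active level; linearly-conditional
#' effects use the active-level slope there and `effect_alt` elsewhere.
#' Metabolite-like variables are then censored: the detection limit is the
#' `censor_fraction` quantile of the variable, values below it are replaced
#' by the limit, and a paired `<name>_cens` switch records 0 (censored) or 1.
#'
#' @param network a `ground_truth_network`.
#' @param config a [sim_config()] (uses `n_samples`, `censor_fraction`,
#'   `seed`).
#' @return list with `data` (a [variable_table()]; censoring switches and
#'   modulators in its discrete block), `modulators` (the true assignments),
#'   and `detection_limits` (named vector for the censored variables).
#' @export
simulate_samples <- function(network, config) {
  stopifnot(inherits(network, "ground_truth_network"),
            inherits(config, "sim_config"))
  if (!is_acyclic(network$nodes, network$edges))
    stop("network must be acyclic")
  with_seed(config$seed + 1L, {
    n <- config$n_samples
    mods <- lapply(network$modulators, function(lv)
      factor(sample(rep_len(lv, n)), levels = lv))
    mods <- as.data.frame(mods, optional = TRUE,
                          row.names = paste0("s", seq_len(n)))
    ord <- topological_order(network$nodes, network$edges)
    x <- matrix(0, n, length(network$nodes),
                dimnames = list(paste0("s", seq_len(n)), network$nodes))
    for (v in ord) {
      inc <- network$edges[network$edges$child == v, , drop = FALSE]
      mu <- rep(0, n)
      for (i in seq_len(nrow(inc))) {
        e <- inc[i, ]
        p <- x[, e$parent]
        mu <- mu + switch(e$class,
          plain = e$effect * p,
          switched = e$effect * p * (mods[[e$modulator]] == e$active_level),
          linear = ifelse(mods[[e$modulator]] == e$active_level,
                          e$effect, e$effect_alt) * p)
      }
      x[, v] <- mu + rnorm(n, 0, network$noise_scale[[v]])
    }
    limits <- c()
    switches <- list()
    if (config$censor_fraction > 0) {
      for (v in names(network$roles)[network$roles == "metabolite"]) {
        d <- quantile(x[, v], config$censor_fraction, names = FALSE)
        sw <- as.integer(x[, v] >= d)
        x[x[, v] < d, v] <- d
        switches[[paste0(v, "_cens")]] <- factor(sw, levels = c(0, 1))
        limits[v] <- d
      }
    }
    disc <- cbind(mods, as.data.frame(switches,
                                      row.names = rownames(mods)))
    list(data = variable_table(x, disc, roles = network$roles),
         modulators = mods, detection_limits = limits)
  })
}

#' Emit probe- and spot-level data from latent variable values
#'
#' Emulates a pangenome-array readout: each latent variable spawns
#' `probes_per_node` probes split round-robin across `n_lineages` strain
#' lineages.  Probes of lineage 1 measure the latent signal itself; other
#' lineages measure independent latent strain signals of the same scale.
#' Each probe adds its own Gaussian noise, is exponentiated to the positive
#' intensity-ratio scale, and is replicated over `n_spots` spots with
#' log-normal spot noise and recorded background statistics.  The annotation
#' carries the ortholog bin (the latent variable) and per-lineage percent
#' identities drawn >= 95 for the target lineage and <= 80 off-target,
#' straddling the 85% strain-differentiation cutoff.
#'
#' @param latent a [variable_table()] of latent values (e.g. from
#'   [simulate_samples()]).
#' @param config a [sim_config()].
#' @return list with `spots` (a spot-level data.frame: probe, sample, spot,
#'   intensity, bg_mean, bg_sd), `annotation` (probe, bin, lineage,
#'   `identity_L*` columns), and `latent_by_probe` (matrix of each probe's
#'   noise-free lineage signal, for oracle checks).
#' @export
emit_probe_level <- function(latent, config) {
  stopifnot(inherits(latent, "variable_table"), inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    x <- latent$continuous
    n <- nrow(x)
    probes <- character(0); bins <- character(0); lineages <- integer(0)
    signal <- NULL
    for (v in colnames(x)) {
      lin_sig <- matrix(NA_real_, n, config$n_lineages)
      lin_sig[, 1L] <- x[, v]
      sdv <- max(sd(x[, v]), 1e-8)
      for (l in seq_len(config$n_lineages)[-1L])
        lin_sig[, l] <- rnorm(n, 0, sdv)
      for (k in seq_len(config$probes_per_node)) {
        l <- ((k - 1L) %% config$n_lineages) + 1L
        probes <- c(probes, sprintf("%s_p%02d", v, k))
        bins <- c(bins, v)
        lineages <- c(lineages, l)
        signal <- cbind(signal, lin_sig[, l])
      }
    }
    colnames(signal) <- probes
    rownames(signal) <- rownames(x)
    probe_val <- signal + matrix(rnorm(length(signal), 0, config$probe_noise),
                                 nrow(signal))
    spots <- do.call(rbind, lapply(seq_along(probes), function(j) {
      do.call(rbind, lapply(seq_len(config$n_spots), function(s) {
        data.frame(probe = probes[j], sample = rownames(x),
                   spot = s,
                   intensity = exp(probe_val[, j] +
                                     rnorm(n, 0, config$spot_noise)),
                   bg_mean = pmax(rnorm(n, config$background_mean,
                                        config$background_sd / 4), 1e-6),
                   bg_sd = abs(rnorm(n, config$background_sd,
                                     config$background_sd / 4)),
                   stringsAsFactors = FALSE)
      }))
    }))
    ident <- matrix(NA_real_, length(probes), config$n_lineages,
                    dimnames = list(probes,
                                    paste0("identity_L", seq_len(config$n_lineages))))
    for (j in seq_along(probes)) {
      ident[j, ] <- runif(config$n_lineages, 60, 80)
      ident[j, lineages[j]] <- runif(1, 95, 100)
    }
    annotation <- data.frame(probe = probes, bin = bins, lineage = lineages,
                             ident, stringsAsFactors = FALSE)
    rownames(annotation) <- NULL
    list(spots = spots, annotation = annotation, latent_by_probe = signal)
  })
}

#' Write the ground truth as GraphML plus a JSON sidecar of edge classes
#'
#' @param network a `ground_truth_network`.
#' @param graphml_path,json_path output paths.
#' @return `graphml_path`, invisibly.
#' @export
write_ground_truth <- function(network, graphml_path, json_path) {
  g <- igraph::graph_from_data_frame(
    network$edges[c("parent", "child", "effect", "class")],
    directed = TRUE,
    vertices = data.frame(name = network$nodes, role = network$roles))
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write the edge-class sidecar")
  jsonlite::write_json(
    list(edges = network$edges, modulators = network$modulators),
    json_path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(graphml_path)
}

#' Synthesize an edge-frequency mixture with a planted low-density plateau
#'
#' Test-bench generator for cutoff detection: edge frequencies are drawn
#' from a dense low-frequency mass, a sparse mid region whose density rises
#' with distance from the plateau center, and a high-confidence cluster, so
#' that the edge-count curve's slope magnitude attains its minimum at the
#' plateau center.
#'
#' @param n_low,n_mid,n_high edge counts in the three components.
#' @param plateau_center center of the low-density plateau in (0, 1).
#' @param seed integer seed.
#' @return numeric vector of edge frequencies in (0, 1].
#' @export
synthesize_edge_frequencies <- function(n_low = 1500, n_mid = 300,
                                        n_high = 400,
                                        plateau_center = 0.6, seed = 1L) {
  with_seed(seed, {
    lo_edge <- 0.36
    hi_edge <- 0.9
    low <- runif(n_low, 0.001, lo_edge)
    # mid-region density rises linearly with distance from the plateau
    # center and spans the whole gap, so the only flat stretch of the edge
    # curve sits at the center itself
    wl <- plateau_center - lo_edge
    wr <- hi_edge - plateau_center
    left <- stats::rbinom(n_mid, 1, wl^2 / (wl^2 + wr^2)) == 1
    mid <- numeric(n_mid)
    mid[left] <- plateau_center - wl * sqrt(runif(sum(left)))
    mid[!left] <- plateau_center + wr * sqrt(runif(sum(!left)))
    high <- runif(n_high, hi_edge, 1)
    c(low, mid, high)
  })
}
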