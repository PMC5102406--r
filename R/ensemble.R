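## Ensemble module: sample acyclic networks from the fragment library,
## tabulate edge frequencies f over the ensemble, validate against an
## exhaustive small-instance oracle, and forward-simulate from the fitted
## local models.

#' @noRd
lib_to_cpp <- function(lib) {
  vars <- names(lib$children)
  idx <- setNames(seq_along(vars) - 1L, vars)
  frag_parents <- lapply(lib$children, function(frags)
    lapply(frags, function(f) as.integer(idx[f$parents])))
  frag_weights <- lapply(lib$children, function(frags) {
    s <- vapply(frags, `[[`, 0, "score")
    exp(s - max(s))
  })
  list(parents = frag_parents, weights = frag_weights, vars = vars)
}

#' @noRd
choices_to_edges <- function(lib, choice) {
  vars <- names(lib$children)
  rows <- lapply(seq_along(vars), function(ci) {
    f <- lib$children[[ci]][[choice[[ci]]]]
    if (!length(f$parents)) return(NULL)
    data.frame(parent = f$parents, child = f$child,
               modulator = f$modulator, class = f$class,
               active_level = f$active_level, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(parent = character(0), child = character(0),
                      modulator = character(0), class = character(0),
                      active_level = character(0))
  out
}

#' Draw a single acyclic network from the fragment library
#'
#' One Gibbs chain (single-child updates restricted to fragments that keep
#' the joint graph acyclic) run for `burn_in` sweeps from the empty
#' network; its end state is the sample.  Fragments are drawn with
#' probability proportional to `exp(score)` among the acyclicity-feasible
#' ones.
#'
#' @param lib a `fragment_library` from [enumerate_fragments()].
#' @param seed integer seed (deterministic output).
#' @param burn_in sweeps per chain; default `50 * n_nodes`.
#' @param max_pair_combos pair-block updates (which allow edge reversals
#'   between dependent variables) are applied only when the two children's
#'   fragment counts multiply to at most this bound (default 4096).
#' @return a `dag_sample`: list with `choice` (fragment index per child),
#'   `fragments` (the chosen fragment objects) and `edges` (data.frame with
#'   modulator annotation).
#' @export
sample_network <- function(lib, seed = 1L, burn_in = NULL,
                           max_pair_combos = 4096) {
  stopifnot(inherits(lib, "fragment_library"))
  enc <- lib_to_cpp(lib)
  n <- length(enc$vars)
  if (is.null(burn_in)) burn_in <- 50L * n
  ch <- with_seed(seed,
    gibbs_sample_networks(enc$parents, enc$weights, n, 1L,
                          as.integer(burn_in),
                          as.integer(max_pair_combos)))[1L, ]
  edges <- choices_to_edges(lib, ch)
  if (!is_acyclic(enc$vars, edges)) stop("internal error: cyclic sample")
  structure(list(choice = setNames(as.integer(ch), enc$vars),
                 fragments = lapply(seq_len(n), function(ci)
                   lib$children[[ci]][[ch[[ci]]]]),
                 edges = edges),
            class = "dag_sample")
}

#' Build an ensemble of sampled networks and tabulate edge frequencies
#'
#' Samples `M` networks as independent Gibbs chains (default 1,000) and
#' summarizes them: for every candidate edge, and for every (edge,
#' modulator, class) combination, the occurrence count and the frequency
#' f = count / M.  The conditional frequency counts only the occurrences
#' carrying that modulator annotation; the marginal edge frequency counts
#' any occurrence.  Each edge also carries the sign r — the Pearson
#' correlation of the two variables across all samples, computed on the
#' data independently of the ensemble.
#'
#' @param lib a `fragment_library`.
#' @param M number of networks (default 1000).
#' @param seed integer seed.
#' @param burn_in Gibbs sweeps per chain; default `50 * n_nodes`.
#' @param max_pair_combos bound on the pair-block move's enumeration size
#'   (see [sample_network()]).
#' @return an `ensemble_summary`: list with `M`, `edges` (parent, child,
#'   count, f, r), `pairs` (undirected relationship frequencies: either
#'   orientation of a node pair counts — within one network the two
#'   orientations are mutually exclusive, and for likelihood-equivalent
#'   structures the directed mass splits between them while the
#'   relationship itself is what the data identify),
#'   `edge_variants` (parent, child, modulator, class,
#'   active_level, count, f, r), `fragments` (per-fragment counts; a
#'   child's frequencies sum to 1), `choices` (M x children matrix) and the
#'   library.
#' @export
build_ensemble <- function(lib, M = 1000L, seed = 1L, burn_in = NULL,
                           max_pair_combos = 4096) {
  stopifnot(inherits(lib, "fragment_library"), M >= 1L)
  enc <- lib_to_cpp(lib)
  n <- length(enc$vars)
  if (is.null(burn_in)) burn_in <- 50L * n
  choices <- with_seed(seed,
    gibbs_sample_networks(enc$parents, enc$weights, n, as.integer(M),
                          as.integer(burn_in),
                          as.integer(max_pair_combos)))
  colnames(choices) <- enc$vars
  cmat <- cor(lib$data$continuous)

  frag_rows <- list(); var_keys <- list(); edge_keys <- list()
  pair_keys <- list()
  for (ci in seq_len(n)) {
    frags <- lib$children[[ci]]
    cnt <- tabulate(choices[, ci], nbins = length(frags))
    for (j in seq_along(frags)) {
      f <- frags[[j]]
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        child = f$child, parents = paste(f$parents, collapse = ","),
        modulator = f$modulator, class = f$class, count = cnt[j],
        f = cnt[j] / M, stringsAsFactors = FALSE)
      if (cnt[j] == 0L || !length(f$parents)) next
      for (p in f$parents) {
        vk <- paste(p, f$child, f$modulator, f$class, f$active_level,
                    sep = "\r")
        var_keys[[vk]] <- (var_keys[[vk]] %||% 0L) + cnt[j]
        ek <- paste(p, f$child, sep = "\r")
        edge_keys[[ek]] <- (edge_keys[[ek]] %||% 0L) + cnt[j]
        # undirected relationship: acyclicity forbids both orientations in
        # one network, so orientation counts are additive per pair
        pk <- paste(min(p, f$child), max(p, f$child), sep = "\r")
        pair_keys[[pk]] <- (pair_keys[[pk]] %||% 0L) + cnt[j]
      }
    }
  }
  split_keys <- function(keys, fields) {
    if (!length(keys))
      return(cbind(as.data.frame(setNames(rep(list(character(0)), length(fields)),
                                          fields)),
                   data.frame(count = integer(0), f = numeric(0),
                              r = numeric(0))))
    parts <- do.call(rbind, strsplit(names(keys), "\r", fixed = TRUE))
    df <- as.data.frame(parts, stringsAsFactors = FALSE)
    names(df) <- fields
    df$count <- as.integer(unlist(keys))
    df$f <- df$count / M
    df$r <- cmat[cbind(df[[1L]], df[[2L]])]
    df[order(-df$f, df[[1L]], df[[2L]]), , drop = FALSE]
  }
  edges <- split_keys(edge_keys, c("parent", "child"))
  edge_variants <- split_keys(var_keys, c("parent", "child", "modulator",
                                          "class", "active_level"))
  pairs <- split_keys(pair_keys, c("parent", "child"))
  rownames(edges) <- rownames(edge_variants) <- rownames(pairs) <- NULL
  structure(list(M = as.integer(M), edges = edges,
                 edge_variants = edge_variants, pairs = pairs,
                 fragments = do.call(rbind, frag_rows),
                 choices = choices, lib = lib, seed = seed,
                 burn_in = burn_in),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary:", x$M, "networks,", nrow(x$edges),
      "distinct edges observed\n")
  invisible(x)
}

#' Serialize ensemble edge frequencies to TSV
#' @param summary an `ensemble_summary`.
#' @param path file path.
#' @param variants write the per-(modulator, class) table instead of the
#'   marginal edge table.
#' @export
write_ensemble <- function(summary, path, variants = FALSE) {
  tab <- if (variants) summary$edge_variants else summary$edges
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
is_acyclic_parent_sets <- function(par_sets, n) {
  indeg <- vapply(par_sets, length, 0L)
  children_of <- vector("list", n)
  for (c in seq_len(n))
    for (p in par_sets[[c]])
      children_of[[p]] <- c(children_of[[p]], c)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in children_of[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == n
}

#' Exhaustive posterior edge probabilities on small instances
#'
#' Enumerates every labeled DAG over the continuous variables (respecting
#' the library's in-degree cap and allowed-parent constraints), weights each
#' DAG by the product of its fragments' exponentiated scores under a uniform
#' structure prior, and returns the normalized per-edge posterior inclusion
#' probabilities.  This is the independent oracle the ensemble sampler is
#' validated against; it is limited to 5 variables.
#'
#' @param lib a `fragment_library` built with `top_fragments = Inf`.
#' @return data.frame (parent, child, posterior) with attribute `n_dags`,
#'   the number of acyclic structures visited, and attribute `variants`, the
#'   per-(edge, modulator, class) posterior table.
#' @export
exact_edge_posterior <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  vars <- names(lib$children)
  n <- length(vars)
  if (n > 5L)
    stop("exhaustive enumeration is refused beyond 5 variables")
  if (n == 1L) {
    out <- data.frame(parent = character(0), child = character(0),
                      posterior = numeric(0))
    attr(out, "n_dags") <- 1L
    return(out)
  }
  idx <- setNames(seq_len(n), vars)
  # group each child's fragments by parent set; weight = sum of exp scores
  groups <- lapply(lib$children, function(frags) {
    keys <- vapply(frags, function(f)
      paste(sort(f$parents), collapse = ","), "")
    mx <- max(vapply(frags, `[[`, 0, "score"))
    w <- vapply(split(seq_along(frags), keys), function(i)
      sum(exp(vapply(frags[i], `[[`, 0, "score") - mx)), 0)
    key_frags <- split(seq_along(frags), keys)
    sets <- lapply(strsplit(names(w), ",", fixed = TRUE), function(s)
      unname(idx[s[nzchar(s)]]))
    list(sets = sets, w = unname(w), frag_ids = key_frags)
  })
  combos <- expand.grid(lapply(groups, function(g) seq_along(g$sets)),
                        KEEP.OUT.ATTRS = FALSE)
  z <- 0; n_dags <- 0L
  edge_w <- new.env(parent = emptyenv())
  var_w <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(combos))) {
    sel <- as.integer(combos[i, ])
    par_sets <- lapply(seq_len(n), function(c) groups[[c]]$sets[[sel[c]]])
    if (!is_acyclic_parent_sets(par_sets, n)) next
    n_dags <- n_dags + 1L
    w <- prod(vapply(seq_len(n), function(c) groups[[c]]$w[[sel[c]]], 0))
    z <- z + w
    for (c in seq_len(n)) {
      g <- groups[[c]]
      for (p in par_sets[[c]]) {
        k <- paste(vars[p], vars[c], sep = "\r")
        edge_w[[k]] <- (edge_w[[k]] %||% 0) + w
      }
      # split the parent-set weight over its fragment variants
      ids <- g$frag_ids[[sel[c]]]
      if (length(par_sets[[c]])) {
        sv <- vapply(lib$children[[c]][ids], `[[`, 0, "score")
        ws <- exp(sv - max(sv))
        ws <- ws / sum(ws)
        for (t in seq_along(ids)) {
          f <- lib$children[[c]][[ids[t]]]
          for (p in f$parents) {
            k <- paste(p, f$child, f$modulator, f$class, sep = "\r")
            var_w[[k]] <- (var_w[[k]] %||% 0) + w * ws[t]
          }
        }
      }
    }
  }
  env_to_df <- function(e, fields) {
    keys <- ls(e)
    if (!length(keys)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(fields)),
                                   fields))
      df$posterior <- numeric(0)
      return(df)
    }
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    df <- as.data.frame(parts, stringsAsFactors = FALSE)
    names(df) <- fields
    df$posterior <- vapply(keys, function(k) e[[k]], 0) / z
    df[order(-df$posterior), , drop = FALSE]
  }
  out <- env_to_df(edge_w, c("parent", "child"))
  rownames(out) <- NULL
  attr(out, "n_dags") <- n_dags
  attr(out, "variants") <- env_to_df(var_w, c("parent", "child", "modulator",
                                              "class"))
  out
}

#' Forward-simulate samples from the fitted ensemble
#'
#' Draws networks uniformly from the ensemble and simulates each draw from
#' the chosen fragments' fitted linear-Gaussian models in topological
#' order.  Discrete modulators are bootstrap-resampled from the observed
#' discrete table so conditional fragments see realistic switch patterns.
#'
#' @param summary an `ensemble_summary`.
#' @param n_draws number of simulated samples.
#' @param seed integer seed.
#' @return a [variable_table()] of simulated values (the resampled discrete
#'   rows in its discrete block).
#' @export
simulate_from_ensemble <- function(summary, n_draws, seed = 1L) {
  stopifnot(inherits(summary, "ensemble_summary"))
  lib <- summary$lib
  vars <- names(lib$children)
  n_obs <- nrow(lib$data$continuous)
  with_seed(seed, {
    net_id <- sample.int(summary$M, n_draws, replace = TRUE)
    boot <- sample.int(n_obs, n_draws, replace = TRUE)
    disc <- lib$data$discrete[boot, , drop = FALSE]
    rownames(disc) <- NULL
    x <- matrix(NA_real_, n_draws, length(vars),
                dimnames = list(NULL, vars))
    for (m in unique(net_id)) {
      rows <- which(net_id == m)
      frags <- lapply(seq_along(vars), function(ci)
        lib$children[[ci]][[summary$choices[m, ci]]])
      names(frags) <- vars
      edges <- choices_to_edges(lib, summary$choices[m, ])
      for (v in topological_order(vars, edges)) {
        f <- frags[[v]]
        mu <- rep(f$coef[["(Intercept)"]], length(rows))
        if (length(f$parents)) {
          sub <- variable_table(x[rows, , drop = FALSE],
                                disc[rows, , drop = FALSE],
                                lib$data$roles)
          design <- fragment_design(sub, f$parents,
                                    if (!is.na(f$modulator)) f$modulator,
                                    if (!is.na(f$active_level)) f$active_level,
                                    f$class)
          mu <- as.numeric(design %*% f$coef)
        }
        x[rows, v] <- mu + rnorm(length(rows), 0, sqrt(f$sigma2))
      }
    }
    variable_table(x, disc, lib$data$roles)
  })
}
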