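# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

# small variable table with one strong edge x1 -> x2
vt_pair <- function(n = 30, effect = 0.9, noise = 0.6, seed = 2, p = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  x[, 2] <- effect * x[, 1] + rnorm(n, 0, noise)
  variable_table(x)
}

# spot table with exact replicate structure and optional "dark" probes
# whose intensities sit below the recorded background threshold everywhere
spot_fixture <- function(n_probes = 10, n_samples = 6, n_spots = 4,
                         dark_fraction = 0, seed = 1) {
  set.seed(seed)
  probes <- sprintf("p%02d", seq_len(n_probes))
  dark <- sample(probes, round(dark_fraction * n_probes))
  rows <- list()
  for (pr in probes) {
    base <- exp(rnorm(n_samples, if (pr %in% dark) -4 else 1, 0.5))
    for (sp in seq_len(n_spots)) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe = pr, sample = sprintf("s%02d", seq_len(n_samples)), spot = sp,
        intensity = base * exp(rnorm(n_samples, 0, 0.05)),
        bg_mean = 0.1, bg_sd = 0.02, stringsAsFactors = FALSE)
    }
  }
  list(spots = do.call(rbind, rows), dark = sort(dark))
}

# probe matrix with ortholog bins of correlated probe groups
collapse_fixture <- function(seed = 4) {
  set.seed(seed)
  n <- 20
  sig1 <- rnorm(n); sig2 <- rnorm(n)
  vals <- rbind(
    # binA: a1 ~ a2 correlated pair, a3 distinct
    a1 = exp(sig1 + rnorm(n, 0, 0.05)),
    a2 = exp(sig1 + rnorm(n, 0, 0.05)) * 1.5,
    a3 = exp(rnorm(n)),
    # binB: two lineage clusters of three probes each
    b1 = exp(sig1 + rnorm(n, 0, 0.05)),
    b2 = exp(sig1 + rnorm(n, 0, 0.05)) * 2,
    b3 = exp(sig1 + rnorm(n, 0, 0.05)),
    b4 = exp(sig2 + rnorm(n, 0, 0.05)),
    b5 = exp(sig2 + rnorm(n, 0, 0.05)) * 3,
    b6 = exp(sig2 + rnorm(n, 0, 0.05)))
  colnames(vals) <- sprintf("s%02d", seq_len(n))
  ann <- data.frame(probe = rownames(vals),
                    bin = c("binA", "binA", "binA",
                            rep("binB", 6)),
                    lineage = c(1, 1, 2, 1, 1, 1, 2, 2, 2),
                    stringsAsFactors = FALSE)
  probe_matrix(vals, ann)
}

# brute-force collapse rule, independent of the implementation: single
# linkage over r > r_min on log intensities, highest-mean representative
brute_collapse <- function(m, r_min = 0.9) {
  keep <- character(0)
  for (b in unique(m$annotation$bin)) {
    pb <- m$annotation$probe[m$annotation$bin == b]
    reps <- character(0)
    groups <- as.list(pb)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i >= j) next
          link <- FALSE
          for (x in groups[[i]]) for (y in groups[[j]]) {
            if (cor(log(m$values[x, ]), log(m$values[y, ])) > r_min)
              link <- TRUE
          }
          if (link) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    for (g in groups) {
      mu <- rowMeans(m$values[g, , drop = FALSE])
      reps <- c(reps, g[order(-mu, g)][1L])
    }
    keep <- c(keep, reps)
  }
  sort(keep)
}

# independent breadth-first expansion for neighborhood checks
brute_bfs <- function(edges, seeds, radius) {
  seen <- seeds
  frontier <- seeds
  for (d in seq_len(radius)) {
    nxt <- unique(c(edges$child[edges$parent %in% frontier],
                    edges$parent[edges$child %in% frontier]))
    frontier <- setdiff(nxt, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  sort(seen)
}
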