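## Preprocessing: spot aggregation, background filtering, ortholog-probe
## collapsing, and censoring + eighth-root transform of the mixed dataset.

#' Probe-by-sample intensity matrix with annotation
#'
#' @param values numeric matrix, probes x samples (intensity ratios, > 0).
#' @param annotation data.frame with at least a `probe` column matching
#'   `rownames(values)`; typically also `bin` (ortholog bin) and per-lineage
#'   `identity_*` columns in [0, 100].
#' @param bg_mean,bg_sd optional probe x sample matrices of background
#'   fluorescence statistics (required by [filter_background()]).
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, annotation = NULL, bg_mean = NULL,
                         bg_sd = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have probe rownames")
  if (is.null(annotation))
    annotation <- data.frame(probe = rownames(values), bin = rownames(values),
                             stringsAsFactors = FALSE)
  if (!all(rownames(values) %in% annotation$probe))
    stop("annotation must cover every probe")
  annotation <- annotation[match(rownames(values), annotation$probe), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(values = values, annotation = annotation,
                 bg_mean = bg_mean, bg_sd = bg_sd),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  invisible(x)
}

#' Aggregate replicate spots into one intensity per probe and sample
#'
#' Intensities of identical probe spots are geometrically averaged.  The
#' background statistics carried forward for each (probe, sample) cell are
#' those of the replicate spot with the largest `bg_mean + 2 * bg_sd`, i.e.
#' the most conservative detection threshold among the replicates.
#'
#' @param spots data.frame with columns `probe`, `sample`, `intensity`
#'   (> 0), and optionally `bg_mean`, `bg_sd`.
#' @param annotation optional probe annotation attached to the result.
#' @return a [probe_matrix()] (probes and samples in sorted order, so the
#'   result is invariant to spot record order).
#' @export
aggregate_spots <- function(spots, annotation = NULL) {
  stopifnot(all(c("probe", "sample", "intensity") %in% names(spots)))
  bad <- which(!is.finite(spots$intensity) | spots$intensity <= 0)
  if (length(bad))
    stop(sprintf("nonpositive intensity at spot record %d (probe %s, sample %s)",
                 bad[1L], spots$probe[bad[1L]], spots$sample[bad[1L]]))
  probes <- sort(unique(spots$probe))
  samples <- sort(unique(spots$sample))
  key <- interaction(factor(spots$probe, probes),
                     factor(spots$sample, samples), drop = FALSE)
  vals <- tapply(spots$intensity, key, geometric_mean)
  values <- matrix(as.numeric(vals), length(probes), length(samples),
                   dimnames = list(probes, samples))
  if (anyNA(values)) stop("every (probe, sample) pair needs >= 1 spot")
  bg_mean <- bg_sd <- NULL
  if (all(c("bg_mean", "bg_sd") %in% names(spots))) {
    pick <- function(m, s) {
      i <- which.max(m + 2 * s)
      c(m[i], s[i])
    }
    bg <- tapply(seq_len(nrow(spots)), key,
                 function(i) pick(spots$bg_mean[i], spots$bg_sd[i]))
    bg_mean <- matrix(vapply(bg, `[`, 0, 1L), length(probes), length(samples),
                      dimnames = dimnames(values))
    bg_sd <- matrix(vapply(bg, `[`, 0, 2L), length(probes), length(samples),
                    dimnames = dimnames(values))
  }
  probe_matrix(values, annotation, bg_mean = bg_mean, bg_sd = bg_sd)
}

#' Remove probes never detected above background
#'
#' A probe is retained iff its intensity exceeds
#' `bg_mean + k * bg_sd` in at least one sample; everything else is
#' removed.  The removed set is recorded on the result as attribute
#' `"removed"` (the run log).
#'
#' @param m a [probe_matrix()] with background statistics.
#' @param k number of background standard deviations (default 2).
#' @return filtered [probe_matrix()], with attributes `removed` (character)
#'   and `retained` (character).
#' @export
filter_background <- function(m, k = 2) {
  stopifnot(inherits(m, "probe_matrix"))
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    stop("invalid parameter: k must be a nonnegative scalar")
  if (is.null(m$bg_mean) || is.null(m$bg_sd))
    stop("background statistics unavailable")
  above <- m$values > m$bg_mean + k * m$bg_sd
  keep <- rowSums(above) >= 1L
  out <- probe_matrix(m$values[keep, , drop = FALSE],
                      m$annotation[keep, , drop = FALSE],
                      m$bg_mean[keep, , drop = FALSE],
                      m$bg_sd[keep, , drop = FALSE])
  attr(out, "removed") <- rownames(m$values)[!keep]
  attr(out, "retained") <- rownames(m$values)[keep]
  out
}

#' Collapse correlated ortholog probes to single representatives
#'
#' Within each ortholog bin, probes are grouped by single-linkage over the
#' relation "Pearson r > r_min", with r computed on log intensities across
#' the samples where both probes are present.  Each group is represented by
#' its highest-mean-intensity probe (ties: lexicographically smallest probe
#' id); probes not exceeding `r_min` with any bin-mate remain singletons.
#'
#' @param m a [probe_matrix()] whose annotation has a `bin` column.
#' @param r_min correlation threshold (strict: probes collapse when
#'   `r > r_min`); default 0.9.
#' @return list with `matrix` (the collapsed [probe_matrix()]) and `report`
#'   (data.frame mapping every input probe to its representative, with the
#'   group id and whether it was retained).
#' @export
collapse_orthologs <- function(m, r_min = 0.9) {
  stopifnot(inherits(m, "probe_matrix"))
  if (ncol(m$values) < 3L)
    stop("at least 3 samples are required to estimate probe correlations")
  if (!"bin" %in% names(m$annotation))
    stop("every probe must be assigned to an ortholog bin")
  probes <- rownames(m$values)
  rep_of <- setNames(probes, probes)
  group_of <- setNames(character(length(probes)), probes)
  for (b in unique(m$annotation$bin)) {
    pb <- probes[m$annotation$bin == b]
    comp <- if (length(pb) == 1L) setNames(1L, pb) else {
      cc <- suppressWarnings(
        cor(t(log(m$values[pb, , drop = FALSE])),
            use = "pairwise.complete.obs"))
      adj <- !is.na(cc) & cc > r_min
      diag(adj) <- TRUE
      # single-linkage groups = connected components of the r > r_min graph
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      setNames(igraph::components(g)$membership, pb)
    }
    for (cid in unique(comp)) {
      members <- names(comp)[comp == cid]
      mu <- rowMeans(m$values[members, , drop = FALSE])
      best <- members[order(-mu, members)][1L]
      rep_of[members] <- best
      group_of[members] <- paste0(b, ".", cid)
    }
  }
  keep <- probes %in% rep_of
  keep_probes <- sort(unique(rep_of))
  out <- probe_matrix(m$values[keep_probes, , drop = FALSE],
                      m$annotation[m$annotation$probe %in% keep_probes, ,
                                   drop = FALSE],
                      if (!is.null(m$bg_mean))
                        m$bg_mean[keep_probes, , drop = FALSE],
                      if (!is.null(m$bg_sd))
                        m$bg_sd[keep_probes, , drop = FALSE])
  report <- data.frame(probe = probes, group = group_of[probes],
                       representative = rep_of[probes],
                       retained = probes %in% keep_probes,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(matrix = out, report = report)
}

#' Censor below-detection values and apply the eighth-root transform
#'
#' Censorable variables (metabolite concentrations, rates, setup parameters
#' with detection limits) that are zero or at/below their detection limit
#' are replaced by the limit — or by 1e-4 when no limit is defined — and
#' their paired censoring switch is set to 0; otherwise the switch is 1.
#' Every continuous value is then eighth-root transformed
#' (x -> x^(1/8)).  Discrete columns are never transformed.
#'
#' @param values numeric matrix/data.frame, samples x variables, raw
#'   nonnegative measurements.
#' @param detection_limits named nonnegative vector of detection limits
#'   (variables without an entry use the 1e-4 substitute when censored).
#' @param censorable character vector of variables that carry a censoring
#'   switch; defaults to `names(detection_limits)`.
#' @param roles optional named roles passed through to the result.
#' @param discrete optional data.frame of discrete variables to carry along.
#' @return a [variable_table()]; each censorable variable `x` has a paired
#'   factor column `x_cens` in the discrete block.
#' @export
censor_and_transform <- function(values, detection_limits = NULL,
                                 censorable = names(detection_limits),
                                 roles = NULL, discrete = NULL) {
  x <- as.matrix(values)
  if (any(x < 0, na.rm = TRUE)) stop("negative raw values are not allowed")
  if (any(!is.null(detection_limits) & detection_limits < 0))
    stop("detection limits must be nonnegative")
  switches <- list()
  for (v in censorable) {
    if (!v %in% colnames(x)) stop("unknown censorable variable: ", v)
    d <- detection_limits[v]
    lim <- if (is.na(d) || is.null(d) || length(d) == 0L) 1e-4 else unname(d)
    censored <- x[, v] <= lim | x[, v] == 0
    x[censored, v] <- lim
    switches[[paste0(v, "_cens")]] <- factor(as.integer(!censored),
                                             levels = c(0, 1))
  }
  zero_elsewhere <- setdiff(colnames(x)[colSums(x == 0) > 0], censorable)
  if (length(zero_elsewhere))
    stop("zero values in non-censorable variable(s): ",
         paste(zero_elsewhere, collapse = ", "),
         " (mark them censorable or supply a detection limit)")
  x <- x^(1 / 8)
  disc <- cbind(if (is.null(discrete))
                  data.frame(row.names = seq_len(nrow(x))) else discrete,
                as.data.frame(switches,
                              row.names = rownames(x) %||%
                                seq_len(nrow(x))))
  variable_table(x, disc, roles)
}

#' Turn a probe matrix into inference-ready transcript variables
#'
#' Transposes to samples x probes and applies the eighth-root transform;
#' transcript intensities are never below detection after filtering, so no
#' censoring switches are created.
#'
#' @param m a [probe_matrix()].
#' @return a [variable_table()] of transcript variables.
#' @export
probes_to_variables <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  censor_and_transform(t(m$values))
}

#' Read a spot-level TSV (probe, sample, intensity, bg_mean, bg_sd)
#' @param path file path.
#' @return data.frame suitable for [aggregate_spots()].
#' @export
read_spot_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_spot_table
#' @param spots spot-level data.frame.
#' @export
write_spot_table <- function(spots, path) {
  write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe x sample TSV (first column = probe id) and optional
#' annotation TSV (probe, bin, lineage identities)
#' @param path matrix TSV path.
#' @param annotation_path optional annotation TSV path.
#' @return a [probe_matrix()].
#' @export
read_probe_matrix <- function(path, annotation_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[-1L])
  rownames(values) <- df[[1L]]
  ann <- if (!is.null(annotation_path))
    read.delim(annotation_path, stringsAsFactors = FALSE)
  probe_matrix(values, ann)
}

#' Minimal GEO series-matrix text reader
#'
#' Extracts the expression table between the series-matrix markers of a GEO
#' series matrix file (plain text, possibly the decompressed form of a
#' `_series_matrix.txt.gz`).
#'
#' @param path path to a series-matrix text file.
#' @return a [probe_matrix()] (no background statistics; GEO matrices are
#'   already aggregated).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (!length(beg) || !length(fin))
    stop("not a GEO series-matrix file: table markers missing")
  tab <- read.delim(text = lines[(beg + 1L):(fin - 1L)],
                    check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[-1L])
  rownames(values) <- as.character(tab[[1L]])
  probe_matrix(values)
}
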