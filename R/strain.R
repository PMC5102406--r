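## Strain-analysis module: lineage assignment from probe-identity tables,
## within/between-lineage classification of consensus edges, and
## lineage-ordered correlograms.

#' Assign probes to strain lineage groups from percent identities
#'
#' A probe is labeled with the lineage whose percent identity meets the
#' cutoff when exactly one lineage qualifies; `"ambiguous"` when two or
#' more qualify (the probe cannot differentiate the lineages) and
#' `"unassigned"` when none does.
#'
#' @param annotation data.frame with a `probe` column and one identity
#'   column per lineage (either named in `identity_cols` or auto-detected
#'   as columns starting with `identity_`); identities in [0, 100].
#' @param cutoff percent-identity cutoff (default 85).
#' @param identity_cols optional named character vector mapping lineage
#'   label -> column name.
#' @return a `lineage_assignment` data.frame (probe, label, identity
#'   columns) with attribute `cutoff`.
#' @export
assign_strain_groups <- function(annotation, cutoff = 85,
                                 identity_cols = NULL) {
  stopifnot("probe" %in% names(annotation))
  if (is.null(identity_cols)) {
    cols <- grep("^identity_", names(annotation), value = TRUE)
    identity_cols <- setNames(cols, sub("^identity_", "", cols))
  }
  if (!length(identity_cols)) stop("no identity columns found")
  idm <- as.matrix(annotation[unname(identity_cols)])
  if (any(idm < 0 | idm > 100, na.rm = TRUE))
    stop("percent identities must lie in [0, 100]")
  qual <- idm >= cutoff
  nq <- rowSums(qual, na.rm = TRUE)
  label <- rep("unassigned", nrow(annotation))
  one <- nq == 1L
  label[one] <- names(identity_cols)[apply(qual[one, , drop = FALSE], 1L,
                                           which.max)]
  label[nq >= 2L] <- "ambiguous"
  out <- data.frame(probe = annotation$probe, label = label,
                    annotation[unname(identity_cols)],
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("lineage_assignment", "data.frame")
  out
}

#' Classify consensus edges as within- or between-lineage
#'
#' Edges whose two endpoints carry distinct lineage labels count as
#' `between`; matching labels count as `within.<label>`.  Edges touching a
#' node with no assignment, an ambiguous probe, or a non-probe node
#' (condition or metabolite variables) are `excluded` and counted
#' separately; the categories partition the consensus edge set.
#'
#' @param net a `consensus_network`.
#' @param assignment a `lineage_assignment`.
#' @return list with `counts` (named integer vector: `within.*`, `between`,
#'   `excluded`) and `details` (per-edge category data.frame).
#' @export
classify_edges <- function(net, assignment) {
  stopifnot(inherits(net, "consensus_network"),
            inherits(assignment, "lineage_assignment"))
  lab <- setNames(assignment$label, assignment$probe)
  cat_of <- function(p, c) {
    lp <- lab[p]; lc <- lab[c]
    if (is.na(lp) || is.na(lc) ||
        lp %in% c("ambiguous", "unassigned") ||
        lc %in% c("ambiguous", "unassigned")) return("excluded")
    if (lp == lc) paste0("within.", lp) else "between"
  }
  details <- net$edges[c("parent", "child")]
  details$category <- mapply(cat_of, net$edges$parent, net$edges$child,
                             USE.NAMES = FALSE)
  lineages <- setdiff(unique(assignment$label),
                      c("ambiguous", "unassigned"))
  cats <- c(paste0("within.", sort(lineages)), "between", "excluded")
  counts <- setNames(integer(length(cats)), cats)
  tab <- table(details$category)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, details = details)
}

#' Lineage-ordered probe correlogram
#'
#' Pairwise Pearson correlations of log probe intensities across all
#' samples (the same scale used by [collapse_orthologs()]), with probes
#' ordered by ortholog bin, then lineage, then probe id — so co-regulated
#' lineage blocks appear as high-correlation blocks.  Constant probes have
#' undefined correlations, reported as `NA`.
#'
#' @param m a [probe_matrix()] whose annotation has `bin` (and ideally
#'   `lineage`) columns.
#' @param probes optional probe subset (or a single bin id).
#' @return a `correlogram`: list with `r` (symmetric matrix, unit diagonal)
#'   and `order` (the annotation rows in display order).
#' @export
correlogram <- function(m, probes = NULL) {
  stopifnot(inherits(m, "probe_matrix"))
  if (ncol(m$values) < 3L) stop("need at least 3 samples")
  ann <- m$annotation
  if (!is.null(probes)) {
    if (length(probes) == 1L && probes %in% ann$bin)
      probes <- ann$probe[ann$bin == probes]
    ann <- ann[ann$probe %in% probes, , drop = FALSE]
  }
  lin <- if ("lineage" %in% names(ann)) ann$lineage else rep("", nrow(ann))
  ord <- order(ann$bin, lin, ann$probe)
  ann <- ann[ord, , drop = FALSE]
  vals <- log(m$values[ann$probe, , drop = FALSE])
  const <- apply(vals, 1L, function(x) sd(x) == 0 || !is.finite(sd(x)))
  r <- suppressWarnings(cor(t(vals), use = "pairwise.complete.obs"))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, order = ann), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("correlogram:", nrow(x$r), "probes\n")
  invisible(x)
}

#' Write a correlogram matrix as TSV
#' @param cg a `correlogram`.
#' @param path file path.
#' @export
write_correlogram <- function(cg, path) {
  write.table(data.frame(probe = rownames(cg$r), cg$r, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe identity table (probe, per-lineage identity columns)
#' @param path TSV path.
#' @return data.frame for [assign_strain_groups()].
#' @export
read_identity_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
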