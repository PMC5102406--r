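## Fragment module: enumerate and score candidate local models — plain,
## switched-conditional and linearly-conditional — for every continuous
## child variable.  The score is a BIC-penalized Gaussian log-likelihood:
## score = logL - (q/2) log n with q counting intercept, slopes and the
## noise variance.

# residual variance floor so noiseless fits keep a finite score
.SIGMA2_FLOOR <- 1e-10

#' @noRd
fragment_design <- function(vt, parents, modulator, active_level, class) {
  n <- nrow(vt$continuous)
  X <- vt$continuous[, parents, drop = FALSE]
  if (class == "plain" || length(parents) == 0L) {
    design <- cbind(`(Intercept)` = rep(1, n), X)
  } else if (class == "switched") {
    ind <- as.numeric(vt$discrete[[modulator]] == active_level)
    Z <- X * ind
    colnames(Z) <- paste0(parents, "|", modulator, "=", active_level)
    design <- cbind(`(Intercept)` = rep(1, n), Z)
  } else if (class == "linear") {
    lv <- levels(vt$discrete[[modulator]])
    blocks <- lapply(lv, function(l) {
      Z <- X * as.numeric(vt$discrete[[modulator]] == l)
      colnames(Z) <- paste0(parents, "|", modulator, "=", l)
      Z
    })
    design <- cbind(`(Intercept)` = rep(1, n), do.call(cbind, blocks))
  } else stop("unknown fragment class: ", class)
  design
}

#' @noRd
fit_local_model <- function(y, design) {
  fit <- lm.fit(design, y)
  if (fit$rank < ncol(design)) return(NULL)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  sigma2 <- max(rss / n, .SIGMA2_FLOOR)
  logl <- -n / 2 * (log(2 * pi * sigma2) + 1)
  q <- ncol(design) + 1L  # slopes + intercept + variance
  list(coef = fit$coefficients, sigma2 = sigma2, logl = logl, q = q,
       score = logl - q / 2 * log(n))
}

#' Score one network fragment
#'
#' Fits the local linear-Gaussian model of `child` on `parents` and returns
#' its penalized score.  A switched-conditional fragment multiplies every
#' parent term by the indicator of the (binary) modulator's active level; a
#' linearly-conditional fragment fits a separate slope per modulator level.
#'
#' @param child name of the continuous child variable.
#' @param parents character vector of continuous parent variables (length
#'   0..K; must not contain `child`).
#' @param data a [variable_table()].
#' @param modulator optional discrete variable name.
#' @param class `"plain"`, `"switched"` or `"linear"`; non-plain classes
#'   require `modulator`.
#' @param active_level modulator level whose indicator gates a switched
#'   fragment (default: last level).
#' @return a `fragment` list: child, parents, modulator, active_level,
#'   class, score, coef (intercept + slopes), sigma2, logl, q.
#' @export
score_fragment <- function(child, parents, data, modulator = NULL,
                           class = c("plain", "switched", "linear"),
                           active_level = NULL) {
  stopifnot(inherits(data, "variable_table"))
  class <- match.arg(class)
  if (child %in% parents) stop("child cannot be its own parent")
  if (anyDuplicated(parents)) stop("degenerate fit: duplicated parent")
  n <- nrow(data$continuous)
  if (n <= length(parents) + 2L)
    stop("need n_samples > |parents| + 2")
  if (class != "plain") {
    if (is.null(modulator) || !modulator %in% names(data$discrete))
      stop("conditional fragments require a declared discrete modulator")
    lv <- levels(data$discrete[[modulator]])
    if (class == "switched" && length(lv) != 2L)
      stop("switched-conditional fragments require a binary modulator")
    if (is.null(active_level)) active_level <- lv[[length(lv)]]
  } else modulator <- active_level <- NULL
  design <- fragment_design(data, parents, modulator, active_level, class)
  fit <- fit_local_model(data$continuous[, child], design)
  if (is.null(fit))
    stop("degenerate fit: singular design for child ", child)
  structure(c(list(child = child, parents = parents,
                   modulator = modulator %||% NA_character_,
                   active_level = active_level %||% NA_character_,
                   class = class),
              fit),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment: %s <- {%s}%s [%s] score %.3f\n", x$child,
              paste(x$parents, collapse = ","),
              if (!is.na(x$modulator))
                paste0(" | ", x$modulator, "=", x$active_level) else "",
              x$class, x$score))
  invisible(x)
}

#' Enumerate and score all candidate fragments
#'
#' For every continuous child, all parent sets of size 0..K over the allowed
#' parents are crossed with no modulator plus every (discrete variable x
#' conditional class) variant.  Discrete variables act only as modulators,
#' never as parents or children.  Condition-type variables (roles `rate`,
#' `setup`) may only have condition-type parents — transcripts never drive
#' setup parameters — while transcripts and metabolites accept any
#' continuous parent.  Rank-deficient designs are dropped.  Per child, the
#' `top_fragments` best-scoring fragments are retained (the empty fragment
#' always survives) to bound sampler cost.
#'
#' @param data a [variable_table()].
#' @param K maximum parent-set size (default 3).
#' @param classes conditional classes to enumerate (default both).
#' @param top_fragments per-child retention cap (default 200; `Inf` keeps
#'   everything, as the exhaustive oracle requires).
#' @return a `fragment_library`: per-child fragment lists plus settings and
#'   the data.
#' @export
enumerate_fragments <- function(data, K = 3,
                                classes = c("switched", "linear"),
                                top_fragments = 200) {
  stopifnot(inherits(data, "variable_table"))
  n <- nrow(data$continuous)
  if (n < 3L) stop("need at least 3 samples")
  if (K >= n - 2L)
    stop("K = ", K, " is too large for ", n,
         " samples; reduce max parents below n - 2")
  vars <- colnames(data$continuous)
  p <- length(vars)
  X <- data$continuous
  cond <- condition_vars(data)
  disc <- names(data$discrete)
  variants <- list(list(modulator = NULL, class = "plain"))
  for (d in disc) {
    lv <- levels(data$discrete[[d]])
    if ("switched" %in% classes && length(lv) == 2L)
      variants <- c(variants, list(list(modulator = d, class = "switched",
                                        active_level = lv[[2L]])))
    if ("linear" %in% classes)
      variants <- c(variants, list(list(modulator = d, class = "linear")))
  }
  # one Gram matrix per variant: all candidate scores drop out of it by
  # small Cholesky solves, so enumeration cost is independent of n
  grams <- lapply(variants, function(v) {
    Z <- if (v$class == "plain") X
    else if (v$class == "switched")
      X * as.numeric(data$discrete[[v$modulator]] == v$active_level)
    else do.call(cbind, lapply(levels(data$discrete[[v$modulator]]),
                               function(l)
                                 X * as.numeric(data$discrete[[v$modulator]] == l)))
    n_lev <- ncol(Z) / p
    list(G = crossprod(cbind(1, Z, X)),
         colmap = function(iv) 1L + as.vector(outer(iv, (seq_len(n_lev) - 1L) * p,
                                                    `+`)),
         ycol_off = 1L + ncol(Z))
  })
  children <- vars
  lib <- lapply(children, function(ch) {
    allowed <- setdiff(if (data$roles[[ch]] %in% c("rate", "setup")) cond
                       else vars, ch)
    sets <- list(character(0))
    for (k in seq_len(min(K, length(allowed))))
      sets <- c(sets, combn(allowed, k, simplify = FALSE))
    meta <- list()
    for (vi in seq_along(variants)) {
      g <- grams[[vi]]
      use <- if (vi == 1L) seq_along(sets) else which(lengths(sets) > 0L)
      idx_sets <- lapply(sets[use], function(S)
        c(1L, if (length(S)) g$colmap(match(S, vars))))
      rss <- rss_from_gram(g$G, idx_sets, g$ycol_off + match(ch, vars))
      sigma2 <- pmax(rss / n, .SIGMA2_FLOOR)
      q <- lengths(idx_sets) + 1L
      sc <- -n / 2 * (log(2 * pi * sigma2) + 1) - q / 2 * log(n)
      meta[[vi]] <- data.frame(set = use, variant = vi, score = sc)
    }
    meta <- do.call(rbind, meta)
    meta <- meta[!is.na(meta$score), , drop = FALSE]
    is_empty <- meta$set == 1L & meta$variant == 1L
    rest <- setdiff(order(-meta$score), which(is_empty))
    if (is.finite(top_fragments))
      rest <- head(rest, max(top_fragments - 1L, 0L))
    meta <- meta[c(which(is_empty), rest), , drop = FALSE]
    # refit the retained fragments to attach coefficients and exact scores
    frags <- lapply(seq_len(nrow(meta)), function(i) {
      v <- variants[[meta$variant[i]]]
      tryCatch(
        score_fragment(ch, sets[[meta$set[i]]], data,
                       modulator = v$modulator, class = v$class,
                       active_level = v$active_level %||% NULL),
        error = function(e) NULL)
    })
    frags[!vapply(frags, is.null, TRUE)]
  })
  names(lib) <- children
  structure(list(children = lib, K = K, score = "bic",
                 top_fragments = top_fragments, data = data),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library:", length(x$children), "children,",
      sum(vapply(x$children, length, 0L)), "fragments (K =", x$K, ")\n")
  invisible(x)
}

#' Serialize a fragment library to TSV for inspection
#' @param lib a `fragment_library`.
#' @param path file path.
#' @export
write_fragment_library <- function(lib, path) {
  rows <- do.call(rbind, lapply(lib$children, function(frags)
    do.call(rbind, lapply(frags, function(f)
      data.frame(child = f$child,
                 parents = paste(f$parents, collapse = ","),
                 modulator = f$modulator, class = f$class,
                 score = f$score, stringsAsFactors = FALSE)))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
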