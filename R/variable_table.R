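#' Mixed continuous/discrete variable table
#'
#' The common container consumed by fragment enumeration and ensemble
#' sampling: one row per sample, continuous variables (transcript
#' intensities, metabolite concentrations, respiration rates, setup
#' parameters) in a numeric matrix and discrete variables (censoring
#' switches, condition switches, tiered acceptor/donor type) as factors.
#' Continuous variables carry a role, which the fragment enumerator uses to
#' impose the causal-ordering prior (condition-type variables may not have
#' transcript parents).
#'
#' @param continuous numeric matrix, samples x variables, with column names.
#' @param discrete data.frame of factors with the same number of rows (may
#'   have zero columns).
#' @param roles named character vector over `colnames(continuous)` with
#'   values in `"transcript"`, `"metabolite"`, `"rate"`, `"setup"`.
#'   Defaults every variable to `"transcript"`.
#' @return object of class `variable_table` with elements `continuous`,
#'   `discrete`, `roles`.
#' @export
variable_table <- function(continuous, discrete = NULL, roles = NULL) {
  continuous <- as.matrix(continuous)
  if (is.null(colnames(continuous)))
    stop("continuous matrix must have column names")
  storage.mode(continuous) <- "double"
  n <- nrow(continuous)
  if (is.null(discrete)) discrete <- data.frame(row.names = seq_len(n))
  discrete <- as.data.frame(discrete, stringsAsFactors = TRUE)
  if (nrow(discrete) != n)
    stop("discrete table must have one row per sample")
  discrete[] <- lapply(discrete, function(x) if (is.factor(x)) x else factor(x))
  if (is.null(roles))
    roles <- setNames(rep("transcript", ncol(continuous)), colnames(continuous))
  roles <- roles[colnames(continuous)]
  bad <- setdiff(unique(roles), c("transcript", "metabolite", "rate", "setup"))
  if (length(bad) || anyNA(roles))
    stop("roles must cover every continuous variable with values in ",
         "transcript/metabolite/rate/setup")
  structure(list(continuous = continuous, discrete = discrete, roles = roles),
            class = "variable_table")
}

#' @export
print.variable_table <- function(x, ...) {
  cat("variable_table:", nrow(x$continuous), "samples,",
      ncol(x$continuous), "continuous,", ncol(x$discrete),
      "discrete variables\n")
  invisible(x)
}

#' @export
dim.variable_table <- function(x) dim(x$continuous)

#' Condition-type continuous variables (allowed parents of everything)
#' @noRd
condition_vars <- function(vt) names(vt$roles)[vt$roles %in% c("rate", "setup")]

#' Write / read a variable table as TSV
#'
#' Layout mirrors the inference input spreadsheets: continuous columns
#' (censorable variables next to their paired `<name>_cens` switch column)
#' followed by the remaining discrete columns.  A `#role:` header line
#' records the role of each continuous variable.
#'
#' @param vt a [variable_table()].
#' @param path file path.
#' @return `write_variable_table` returns `path` invisibly;
#'   `read_variable_table` returns a [variable_table()].
#' @export
write_variable_table <- function(vt, path) {
  stopifnot(inherits(vt, "variable_table"))
  df <- cbind(data.frame(sample = rownames(vt$continuous) %||%
                           paste0("s", seq_len(nrow(vt$continuous)))),
              as.data.frame(vt$continuous),
              vt$discrete)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#role:\t", paste(names(vt$roles), vt$roles,
                                      sep = "=", collapse = "\t")), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_variable_table
#' @export
read_variable_table <- function(path) {
  first <- readLines(path, n = 1L)
  roles <- NULL
  skip <- 0L
  if (startsWith(first, "#role:")) {
    skip <- 1L
    kv <- strsplit(strsplit(sub("^#role:\t", "", first), "\t")[[1]], "=")
    roles <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rn <- df$sample
  df$sample <- NULL
  cont_names <- if (is.null(roles)) names(df)[vapply(df, is.numeric, TRUE)]
                else names(roles)
  cont <- as.matrix(df[cont_names])
  rownames(cont) <- rn
  disc <- df[setdiff(names(df), cont_names)]
  disc[] <- lapply(disc, factor)
  variable_table(cont, disc, roles)
}
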