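#' Clustered binary data panel
#'
#' Bundles a clustered binary dataset in the long format used throughout
#' the package: one row per observation, with a binary outcome, a cluster
#' identifier, fixed-effect covariates and random-effect covariates.
#' Clusters are contiguous blocks in order of first appearance; the
#' within-cluster order is the row order of the input.
#'
#' @param y binary outcome vector (0/1).
#' @param X fixed-effects design matrix (n rows).
#' @param W random-effects design matrix (n rows).
#' @param id cluster identifier vector (n values).
#' @return an object of class `sgtlm_panel` with elements `y`, `X`, `W`,
#'   `id` and `index` (a list of row indices per cluster).
#' @export
sgtlm_panel <- function(y, X, W, id) {
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(X) || anyNA(W) || anyNA(id))
    stop("missing values are not allowed in a panel")
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1; found value(s): ",
         paste(head(setdiff(unique(y), c(0, 1))), collapse = ", "))
  X <- as.matrix(X); W <- as.matrix(W)
  storage.mode(X) <- storage.mode(W) <- "double"
  if (nrow(X) != length(y) || nrow(W) != length(y) ||
      length(id) != length(y))
    stop("y, X, W and id must have matching numbers of rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  idx <- split(seq_along(y), factor(id, levels = unique(id)))
  if (any(lengths(idx) < 1L)) stop("every cluster must be non-empty")
  structure(list(y = y, X = X, W = W, id = id, index = idx),
            class = "sgtlm_panel")
}

#' @export
print.sgtlm_panel <- function(x, ...) {
  ni <- lengths(x$index)
  cat("Clustered binary panel:", length(x$y), "observations in",
      length(x$index), "clusters (sizes ", min(ni), "-", max(ni), ")\n",
      sep = " ")
  cat("  outcome prevalence:", round(mean(x$y), 3), "\n")
  cat("  fixed covariates: ", paste(colnames(x$X), collapse = ", "), "\n")
  cat("  random covariates:", paste(colnames(x$W), collapse = ", "), "\n")
  invisible(x)
}

.build_design <- function(data, cols, what) {
  if (length(cols) == 0L) stop("no ", what, " covariates specified")
  out <- matrix(0, nrow(data), length(cols),
                dimnames = list(NULL, ifelse(cols == "1", "(Intercept)",
                                             cols)))
  for (j in seq_along(cols)) {
    if (cols[j] == "1") {
      out[, j] <- 1
    } else {
      if (!cols[j] %in% names(data))
        stop("column '", cols[j], "' not found in the data")
      v <- data[[cols[j]]]
      if (!is.numeric(v)) stop("column '", cols[j], "' must be numeric")
      out[, j] <- v
    }
  }
  out
}

#' Build a panel from a long-format data frame
#'
#' @param data a data frame in long format.
#' @param outcome name of the binary outcome column.
#' @param id name of the cluster identifier column.
#' @param fixed character vector of fixed-effect covariate columns; the
#'   pseudo-column `"1"` inserts an intercept.
#' @param random character vector of random-effect covariate columns
#'   (`"1"` for a random intercept).
#' @return an `sgtlm_panel`.
#' @export
as_panel <- function(data, outcome, id, fixed, random) {
  data <- as.data.frame(data)
  for (col in c(outcome, id))
    if (!col %in% names(data)) stop("column '", col, "' not found")
  sgtlm_panel(data[[outcome]], .build_design(data, fixed, "fixed"),
              .build_design(data, random, "random"), data[[id]])
}

#' Read a long-format CSV file into a panel
#'
#' @param path path to a CSV file with a header row.
#' @inheritParams as_panel
#' @return an `sgtlm_panel`.
#' @export
read_panel_csv <- function(path, outcome, id, fixed, random) {
  as_panel(read.csv(path), outcome, id, fixed, random)
}

#' Write a panel back to a long-format CSV file
#'
#' The outcome, id and covariate columns are written with their panel
#' column names; reading the file back with [read_panel_csv()] and the
#' same schema round-trips the panel.
#'
#' @param panel an `sgtlm_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  keep_x <- colnames(panel$X) != "(Intercept)"
  keep_w <- colnames(panel$W) != "(Intercept)"
  df <- data.frame(id = panel$id, y = panel$y,
                   panel$X[, keep_x, drop = FALSE],
                   panel$W[, keep_w, drop = FALSE], check.names = FALSE)
  df <- df[, !duplicated(names(df)), drop = FALSE]
  # serialize doubles with 17 significant digits so the decimal text
  # parses back to the identical binary value (exact round trip)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
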