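#' Methylation beta-value matrices
#'
#' A `beta_matrix` wraps a probes-by-samples numeric matrix of methylation
#' fractions (beta values in `[0, 1]`, `NA` for missing cells), an optional
#' matching matrix of detection p-values, and a platform label. Row names are
#' probe identifiers, column names are sample identifiers.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs). Values in `[0, 1]` or `NA`.
#' @param detection_p Optional numeric matrix of per-cell detection p-values
#'   with the same dimensions and dimnames as `values`.
#' @param platform Character scalar labelling the array platform.
#'
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, detection_p = NULL, platform = "platform_a") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry probe IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate probe IDs in `values`.")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("beta values must lie in [0, 1] where present.")
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values))) {
      abort("`detection_p` must have the same dimensions as `values`.")
    }
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, detection_p = detection_p,
         platform = as.character(platform)[1]),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, platform '%s'\n",
              nrow(x$values), ncol(x$values), x$platform))
  cat(sprintf("  missing cells: %d (%.2f%%)%s\n",
              sum(is.na(x$values)),
              100 * mean(is.na(x$values)),
              if (is.null(x$detection_p)) "" else "; detection p present"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers of a beta matrix
#' @param x A `beta_matrix`.
#' @return Character vector of IDs.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert between tabular and matrix beta representations
#'
#' The on-disk (TSV) shape is a data frame whose first column (`probe_id`)
#' holds probe identifiers and whose remaining columns are samples; this is
#' also the shape pipe-friendly code passes around.
#'
#' @param x A data frame in TSV shape, or a numeric matrix with dimnames.
#' @inheritParams beta_matrix
#' @return A `beta_matrix`.
#' @export
as_beta_matrix <- function(x, detection_p = NULL, platform = "platform_a") {
  if (inherits(x, "beta_matrix")) return(x)
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
    storage.mode(m) <- "double"
    return(beta_matrix(m, detection_p = detection_p, platform = platform))
  }
  beta_matrix(x, detection_p = detection_p, platform = platform)
}

#' @export
as.data.frame.beta_matrix <- function(x, ...) {
  cbind(data.frame(probe_id = probe_ids(x), stringsAsFactors = FALSE),
        as.data.frame(x$values))
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.beta_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.beta_matrix(x))
}

#' Read / write beta matrices as TSV
#'
#' Probes are rows, samples are columns, first column `probe_id`.
#'
#' @param path File path.
#' @inheritParams beta_matrix
#' @return `read_beta_tsv()` a `beta_matrix`; `write_beta_tsv()` the path,
#'   invisibly.
#' @export
read_beta_tsv <- function(path, platform = "platform_a") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_beta_matrix(df, platform = platform)
}

#' @rdname read_beta_tsv
#' @param x A `beta_matrix` or TSV-shaped data frame.
#' @export
write_beta_tsv <- function(x, path) {
  df <- if (inherits(x, "beta_matrix")) as.data.frame(x) else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Beta / M-value transforms
#'
#' `beta_to_m()` maps methylation fractions to M-values,
#' `M = log2(beta / (1 - beta))`; `m_to_beta()` is its inverse,
#' `beta = 2^M / (1 + 2^M)`. Betas are clipped to `[eps, 1 - eps]` before the
#' logit-like transform so boundary values stay finite.
#'
#' @param x Numeric vector/matrix of beta values, or a `beta_matrix` (the
#'   transform is applied to its values and a plain matrix is returned).
#' @param eps Clipping bound, default `1e-6`.
#' @return Numeric object of the same shape.
#' @export
beta_to_m <- function(x, eps = 1e-6) {
  if (inherits(x, "beta_matrix")) x <- x$values
  x <- pmin(pmax(x, eps), 1 - eps)
  log2(x / (1 - x))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(x) {
  if (inherits(x, "beta_matrix")) x <- x$values
  p <- 2^x
  p / (1 + p)
}
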