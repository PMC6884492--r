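# Davies-Bouldin univariate feature screening.

#' Two-class Davies-Bouldin index of a single feature
#'
#' For one feature and binary labels, the index is
#' `(S1 + S2) / |m1 - m2|` where `m` are the class means and `S` the mean
#' absolute deviations from them. Small values indicate well-separated,
#' compact classes; features with coincident class means score `Inf`.
#'
#' @param values Numeric feature values.
#' @param labels Binary labels (logical, factor or two-level vector).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
davies_bouldin_index <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) == 0)) stop("both classes must be non-empty", call. = FALSE)
  x1 <- values[labels == levels(labels)[1]]
  x2 <- values[labels == levels(labels)[2]]
  m1 <- mean(x1)
  m2 <- mean(x2)
  s1 <- mean(abs(x1 - m1))
  s2 <- mean(abs(x2 - m2))
  d <- abs(m1 - m2)
  if (d == 0) return(Inf)  # coincident centroids: never separable
  (s1 + s2) / d
}

#' Select features by Davies-Bouldin index
#'
#' @param x Data frame or matrix of features (columns) by observations
#'   (rows).
#' @param labels Binary labels aligned to rows.
#' @param threshold Keep features with DBI strictly below this value
#'   (default 2, the published criterion).
#' @return Character vector of selected feature names, ascending by DBI,
#'   with the DBI values as attribute `dbi`.
#' @export
select_features <- function(x, labels, threshold = 2) {
  x <- as.data.frame(x)
  dbi <- vapply(x, davies_bouldin_index, numeric(1), labels = labels)
  keep <- which(dbi < threshold)
  if (!length(keep)) {
    stop("no feature has DBI < ", threshold,
         "; consider raising the threshold", call. = FALSE)
  }
  ord <- keep[order(dbi[keep])]
  structure(names(x)[ord], dbi = dbi[ord])
}
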