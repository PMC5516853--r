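#' Z-score normalise an expression matrix per gene
#'
#' Centres and scales each gene row to mean 0, standard deviation 1 across
#' samples. Zero-variance rows cannot be scaled; they are mapped to
#' all-zeros with a warning (such genes carry no co-variation signal and
#' are dropped by feature selection anyway).
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param sd `"sample"` (n-1 denominator, default; conventional for small
#'   replicate counts) or `"population"` (n denominator).
#' @return matrix of the same shape and ordering.
#' @export
zscore_normalize <- function(x, sd = c("sample", "population")) {
  sd <- match.arg(sd)
  check_expression_matrix(x)
  if (ncol(x) < 2) stop("need >=2 samples to normalise", call. = FALSE)
  ddof <- if (sd == "sample") 1 else 0
  mu <- rowMeans(x)
  s <- sqrt(row_variances(x, ddof = ddof))
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance gene(s) mapped to all-zero rows: %s",
                    sum(zero),
                    paste(utils::head(rownames(x)[zero], 5), collapse = ", ")),
            call. = FALSE)
    s[zero] <- 1
  }
  z <- (x - mu) / s
  z[zero, ] <- 0
  z
}

#' Select high-variance genes
#'
#' Ranks genes by descending across-sample variance (ties broken by gene
#' identifier, so the ranking is invariant to input row order) and retains
#' either the `k` most variable genes or the prefix up to the elbow of the
#' sorted variance curve.
#'
#' The elbow is located geometrically: for the sorted variance curve, the
#' candidate index `e` maximises the perpendicular distance to the chord
#' joining the curve's endpoints; if the curve at `e` has already fallen
#' below the chord the elbow is taken one position earlier, so only the
#' high-variance plateau before the drop is kept.
#'
#' @param x numeric genes x samples matrix.
#' @param method `"elbow"` (default) or `"top_k"`.
#' @param k number of genes for `method = "top_k"`.
#' @return the submatrix of retained genes, ordered by descending variance.
#' @export
select_features <- function(x, method = c("elbow", "top_k"), k = NULL) {
  method <- match.arg(method)
  check_expression_matrix(x)
  v <- row_variances(x)
  ord <- order(-v, rownames(x), method = "radix")
  v_sorted <- v[ord]
  if (method == "top_k") {
    if (!is_count(k, min = 2)) {
      stop("`k` must be an integer >= 2 for top_k selection", call. = FALSE)
    }
    if (k > nrow(x)) stop("`k` exceeds the number of genes", call. = FALSE)
    keep <- ord[seq_len(k)]
  } else {
    n_keep <- elbow_index(v_sorted)
    if (is.na(n_keep)) {
      warning("degenerate variance curve (all variances equal); ",
              "retaining all genes", call. = FALSE)
      n_keep <- nrow(x)
    }
    if (n_keep < 2) {
      stop("elbow selection would retain fewer than 2 genes; ",
           "the weight matrix is undefined", call. = FALSE)
    }
    keep <- ord[seq_len(n_keep)]
  }
  x[keep, , drop = FALSE]
}

#' Elbow index of a descending curve
#'
#' Returns the number of leading points to keep on a sorted (descending)
#' curve, via the maximum-perpendicular-distance-to-chord rule described in
#' [select_features()]. Returns `NA` for a flat curve (no elbow).
#'
#' @param v numeric vector sorted in descending order.
#' @return integer index, or `NA` if the curve is degenerate.
#' @export
elbow_index <- function(v) {
  n <- length(v)
  if (n <= 2) return(n)
  if (max(v) == min(v)) return(NA_integer_)
  i <- seq_len(n)
  # chord from (1, v[1]) to (n, v[n]); signed vertical offset has the same
  # argmax pattern as the perpendicular distance (constant slope factor)
  chord <- v[1] + (v[n] - v[1]) * (i - 1) / (n - 1)
  off <- v - chord
  e <- which.max(abs(off))
  if (off[e] < 0) e <- e - 1L
  max(e, 1L)
}

#' Discretise a normalised matrix to ternary Hopfield states
#'
#' Entries above `threshold` map to `+1`, below `-threshold` to `-1`, the
#' dead zone in between to `0`. Intended for per-gene z-scores, where a
#' symmetric threshold gives all three states nonzero mass.
#'
#' @param x numeric genes x samples matrix (z-scored per gene).
#' @param threshold positive dead-zone half-width (default 0.5).
#' @return integer matrix with entries in `{-1, 0, +1}` and the same
#'   dimnames as `x`.
#' @export
discretize <- function(x, threshold = 0.5) {
  if (!is_number(threshold) || threshold <= 0) {
    stop("`threshold` must be a positive number", call. = FALSE)
  }
  check_expression_matrix(x)
  h <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  h[x > threshold] <- 1L
  h[x < -threshold] <- -1L
  h
}
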