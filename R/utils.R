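# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic linear-congruential mixing of a master seed with a stream
#' identifier and an index, so that every randomised step of an analysis
#' (one perturbation repeat, one baseline draw, ...) gets its own
#' reproducible seed. All returned seeds lie in `[1, 2^31 - 23)`.
#'
#' @param master integer master seed.
#' @param stream small integer identifying the consumer (e.g. 1 =
#'   perturbation draws, 2 = random-network baselines).
#' @param index integer counter within the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream = 0L, index = 0L) {
  m <- 2147483629 # largest prime < 2^31
  x <- (as.double(master) %% m) * 48271 + as.double(stream) * 75007 +
    as.double(index) * 65537
  as.integer(x %% m + 1)
}

# Validate a genes x samples expression matrix: numeric, unique dimnames,
# no missing values. `what` names the argument in error messages.
check_expression_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", what),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene row names and sample column names", what),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop(sprintf("duplicate gene identifiers in `%s`: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop(sprintf("duplicate sample identifiers in `%s`: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("`%s` contains missing values; impute or filter first", what),
         call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

# Row variances without building an apply() closure per call.
row_variances <- function(x, ddof = 1) {
  n <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  ss / (n - ddof)
}
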