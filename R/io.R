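#' Read a genes x samples expression matrix from delimited text
#'
#' Expects genes in rows, the first column holding gene identifiers and the
#' header row holding sample identifiers. The delimiter is auto-detected
#' (tab or comma) unless forced.
#'
#' @param path path to a TSV/CSV file.
#' @param sep `"auto"` (default), `"\t"` or `","`.
#' @return a numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path, sep = c("auto", "\t", ",")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (sep == "auto") sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"", fill = FALSE)
  if (ncol(tab) < 2) {
    stop("expression table needs a gene-id column plus >=1 sample column",
         call. = FALSE)
  }
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifiers: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  vals <- tab[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  check_expression_matrix(x, "expression matrix")
  x
}

#' Write an expression (or weight) matrix as delimited text
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @param id_column header of the identifier column.
#' @export
write_expression <- function(x, path, sep = "\t", id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Construct a stage annotation
#'
#' Maps each sample to a developmental stage and fixes the stage order
#' (the developmental progression). Stage order defaults to first
#' appearance in `stages`.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param stages character vector, one stage label per sample.
#' @param stage_order optional explicit ordering of the stage labels.
#' @return a `stage_annotation`: a data frame with columns `sample_id` and
#'   `stage` (a factor whose levels are the stage order).
#' @export
stage_annotation <- function(sample_ids, stages, stage_order = NULL) {
  sample_ids <- as.character(sample_ids)
  stages <- as.character(stages)
  if (length(sample_ids) != length(stages)) {
    stop("`sample_ids` and `stages` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in annotation", call. = FALSE)
  }
  stage_order <- stage_order %||% unique(stages)
  if (!setequal(stage_order, unique(stages)) ||
      length(stage_order) != length(unique(stage_order))) {
    stop("`stage_order` must be a permutation of the observed stage labels",
         call. = FALSE)
  }
  if (length(stage_order) < 2) {
    stop("need at least 2 stages", call. = FALSE)
  }
  ann <- data.frame(sample_id = sample_ids,
                    stage = factor(stages, levels = stage_order),
                    stringsAsFactors = FALSE)
  class(ann) <- c("stage_annotation", "data.frame")
  ann
}

#' @export
print.stage_annotation <- function(x, ...) {
  cat(sprintf("Stage annotation: %d samples, %d stages (%s)\n",
              nrow(x), nlevels(x$stage),
              paste(levels(x$stage), collapse = " -> ")))
  invisible(x)
}

#' Stage order of an annotation
#' @param ann a `stage_annotation`.
#' @return character vector of stage labels in developmental order.
#' @export
stage_order <- function(ann) levels(ann$stage)

# Samples annotated to one stage, in annotation order.
samples_of <- function(ann, stage) ann$sample_id[ann$stage == stage]

#' Read a sample -> stage annotation table
#'
#' Two-column delimited text (`sample_id`, `stage`); a header row is
#' detected and skipped. Stage order is first appearance unless given.
#'
#' @inheritParams read_expression
#' @param stage_order optional explicit stage order.
#' @export
read_stage_annotation <- function(path, stage_order = NULL,
                                  sep = c("auto", "\t", ",")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (sep == "auto") sep <- detect_sep(path)
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"", fill = FALSE)
  if (ncol(tab) != 2) {
    stop("stage annotation must have exactly 2 columns (sample_id, stage)",
         call. = FALSE)
  }
  if (tolower(tab[1, 1]) %in% c("sample", "sample_id") ) {
    tab <- tab[-1, , drop = FALSE]
  }
  stage_annotation(tab[[1]], tab[[2]], stage_order = stage_order)
}

#' Write a stage annotation table
#' @param ann a `stage_annotation`.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_stage_annotation <- function(ann, path, sep = "\t") {
  out <- data.frame(sample_id = ann$sample_id,
                    stage = as.character(ann$stage))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check that an annotation covers exactly the samples of a matrix and that
# every stage retains at least one sample.
validate_annotation <- function(ann, x) {
  if (!inherits(ann, "stage_annotation")) {
    stop("`ann` must be a stage_annotation", call. = FALSE)
  }
  if (!setequal(ann$sample_id, colnames(x)) ||
      nrow(ann) != ncol(x)) {
    stop("annotation samples do not match matrix columns exactly",
         call. = FALSE)
  }
  n_per <- table(ann$stage)
  if (any(n_per == 0)) {
    stop("stage(s) without samples: ",
         paste(names(n_per)[n_per == 0], collapse = ", "), call. = FALSE)
  }
  invisible(ann)
}
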