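#' Build the co-expression weight matrix
#'
#' Edge weights are the Pearson correlations of gene pairs across all
#' samples (pooled over stages, so the whole time course maps onto one
#' static landscape). The diagonal is forced to exactly zero and the matrix
#' is exactly symmetrised, giving the zero-diagonal symmetric weight matrix
#' of a Hopfield network.
#'
#' @param x numeric genes x samples matrix (continuous, typically z-scored
#'   and feature-selected).
#' @return an n x n numeric matrix with gene dimnames, entries in
#'   `[-1, 1]`, zero diagonal, exactly symmetric.
#' @export
build_weight_matrix <- function(x) {
  check_expression_matrix(x)
  if (nrow(x) < 2) stop("need >=2 genes to build a weight matrix",
                        call. = FALSE)
  if (ncol(x) < 3) stop("need >=3 samples to estimate correlations",
                        call. = FALSE)
  v <- row_variances(x)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "),
         "; remove before building the weight matrix", call. = FALSE)
  }
  w <- stats::cor(t(x))
  w <- (w + t(w)) / 2
  w[w > 1] <- 1
  w[w < -1] <- -1
  diag(w) <- 0
  w
}

#' Hopfield energy of one or many network states
#'
#' The energy of a state vector `H` over weight matrix `W` is the quadratic
#' form `E = -1/2 * H W H^T`. Low energy means the ternary state agrees
#' with the stored co-expression structure (tightly co-varying genes take
#' concordant states); it is unitless and scales linearly with the number
#' of agreeing pairs.
#'
#' @param state a ternary state vector of length n, or a genes x samples
#'   matrix of states (one column per sample).
#' @param W n x n symmetric zero-diagonal weight matrix.
#' @return a single energy, or a named vector of per-sample energies when
#'   `state` is a matrix.
#' @export
hopfield_energy <- function(state, W) {
  if (is.matrix(state)) {
    if (nrow(state) != nrow(W)) {
      stop("state/weight dimension mismatch: ", nrow(state), " vs ", nrow(W),
           call. = FALSE)
    }
    check_gene_order(rownames(state), rownames(W))
    s <- state * 1.0
    return(-0.5 * colSums(s * (W %*% s)))
  }
  if (length(state) != nrow(W)) {
    stop("state/weight dimension mismatch: ", length(state), " vs ", nrow(W),
         call. = FALSE)
  }
  check_gene_order(names(state), rownames(W))
  s <- as.numeric(state)
  drop(-0.5 * (s %*% W %*% s))
}

check_gene_order <- function(a, b) {
  if (!is.null(a) && !is.null(b) && !identical(unname(a), unname(b))) {
    stop("gene order of state and weight matrix differ", call. = FALSE)
  }
  invisible(NULL)
}

#' Per-sample and per-stage Hopfield energies
#'
#' Scores every sample's ternary state against the weight matrix and
#' averages within stages. Energies are computed directly from the observed
#' states, without any recall iteration, so they describe the biological
#' states as measured rather than network attractors.
#'
#' @param states integer genes x samples ternary state matrix.
#' @param W weight matrix over the same genes.
#' @param ann a [stage_annotation()] covering every sample.
#' @param stage_method `"mean"` (default): stage energy is the arithmetic
#'   mean of its samples' energies. `"centroid"`: stage energy is the
#'   energy of the stage's consensus (sign-of-mean) state, offered for
#'   comparison.
#' @return an `energy_profile`: list with `per_sample` (named numeric),
#'   `per_stage` (named numeric in stage order), `stage_order`, and the
#'   annotation.
#' @export
stage_energies <- function(states, W, ann,
                           stage_method = c("mean", "centroid")) {
  stage_method <- match.arg(stage_method)
  validate_annotation(ann, states)
  e <- hopfield_energy(states, W)
  stages <- stage_order(ann)
  per_stage <- vapply(stages, function(sg) {
    ids <- samples_of(ann, sg)
    if (stage_method == "mean") {
      mean(e[ids])
    } else {
      hopfield_energy(stage_consensus(states, ann, sg), W)
    }
  }, numeric(1))
  structure(list(per_sample = e, per_stage = per_stage,
                 stage_order = stages, annotation = ann,
                 stage_method = stage_method),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("Hopfield energy profile (%d samples, stage method: %s)\n",
              length(x$per_sample), x$stage_method))
  print(round(x$per_stage, 3))
  invisible(x)
}

#' @export
as.data.frame.energy_profile <- function(x, ...) {
  ann <- x$annotation
  data.frame(sample_id = ann$sample_id,
             stage = as.character(ann$stage),
             energy = unname(x$per_sample[ann$sample_id]),
             stringsAsFactors = FALSE)
}

#' Write an energy profile to TSV or JSON
#'
#' TSV is long format (`sample_id`, `stage`, `energy`); JSON bundles the
#' per-sample and per-stage energies with the stage order.
#'
#' @param profile an `energy_profile`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_energy_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(per_sample = as.list(profile$per_sample),
           per_stage = as.list(profile$per_stage),
           stage_order = profile$stage_order,
           stage_method = profile$stage_method),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Asynchronous Hopfield recall
#'
#' Repeatedly sweeps the nodes in fixed index order, setting each node to
#' the sign of its weighted input field (`sign(0)` leaves the node
#' unchanged, which also covers the ternary 0 state). Under asynchronous
#' updates the energy is a Lyapunov function: it never increases, and the
#' dynamics stop at a fixed point (an attractor) or after `max_sweeps`.
#'
#' Recall explores attractors; it is intentionally *not* used when
#' profiling biological states, whose energies are computed from the
#' observed patterns directly.
#'
#' @param state ternary state vector (length n).
#' @param W weight matrix.
#' @param max_sweeps maximum number of full sweeps (default 100).
#' @param mode update schedule; only `"asynchronous"` is supported, as
#'   synchronous updates do not guarantee energy descent.
#' @return list with `state` (final state), `trajectory` (energy after
#'   each sweep; length 1 if the input is already a fixed point),
#'   `sweeps`, and `converged`.
#' @export
hopfield_recall <- function(state, W, max_sweeps = 100,
                            mode = "asynchronous") {
  mode <- match.arg(mode, "asynchronous")
  if (!is_count(max_sweeps)) stop("`max_sweeps` must be a positive integer",
                                  call. = FALSE)
  if (length(state) != nrow(W)) {
    stop("state/weight dimension mismatch", call. = FALSE)
  }
  check_gene_order(names(state), rownames(W))
  h <- as.numeric(state)
  n <- length(h)
  trajectory <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      field <- sum(W[i, ] * h)
      if (field > 0 && h[i] != 1) {
        h[i] <- 1; changed <- TRUE
      } else if (field < 0 && h[i] != -1) {
        h[i] <- -1; changed <- TRUE
      }
    }
    trajectory <- c(trajectory, -0.5 * drop(h %*% W %*% h))
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  out_state <- as.integer(h)
  names(out_state) <- names(state) %||% rownames(W)
  list(state = out_state, trajectory = trajectory,
       sweeps = length(trajectory), converged = converged)
}

#' Write a weight matrix as tabular text
#'
#' @param W weight matrix with gene dimnames.
#' @param path output path.
#' @export
write_weight_matrix <- function(W, path) {
  write_expression(W, path, id_column = "gene_id")
}

#' Read a weight matrix written by [write_weight_matrix()]
#' @param path input path.
#' @export
read_weight_matrix <- function(path) {
  w <- read_expression(path)
  if (nrow(w) != ncol(w) || !identical(rownames(w), colnames(w))) {
    stop("not a square gene x gene weight matrix", call. = FALSE)
  }
  w
}
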