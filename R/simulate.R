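#' Design of a synthetic stage-structured expression time course
#'
#' Encodes the statistical structure the landscape model assumes: genes
#' organised in co-regulated modules whose within-module co-variation is
#' tight at the endpoint stages and loosened at the transient middle
#' stages, with a subset of modules flipping activation sign between the
#' first and last stage (the ground-truth switched genes). The resulting
#' per-stage energies trace the characteristic arc: low at both endpoints,
#' high in the middle.
#'
#' @param n_genes total number of genes (default 200).
#' @param n_stages number of stages, >= 3 (default 4).
#' @param replicates_per_stage samples per stage, >= 2 (default 10).
#' @param endpoint_coherence signal amplitude (within-module correlation
#'   strength) at the first and last stage, in `(0, 1]` (default 0.9).
#' @param transient_coherence amplitude at middle stages, in
#'   `[0, endpoint_coherence)` (default 0.2).
#' @param n_modules number of co-regulated gene blocks (default 4).
#' @param switch_fraction fraction of modules whose sign flips between the
#'   first and last stage, in `[0, 1]` (default 0.5).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.3).
#' @param factor_sd dispersion of the per-sample module factor around its
#'   unit mean (default 0.2); the unit mean anchors stage-level consensus
#'   signs while the dispersion carries the within-stage co-variation.
#' @param seed integer seed (default 7).
#' @return an `arc_design` list.
#' @export
arc_design <- function(n_genes = 200, n_stages = 4,
                       replicates_per_stage = 10,
                       endpoint_coherence = 0.9, transient_coherence = 0.2,
                       n_modules = 4, switch_fraction = 0.5,
                       noise_sd = 0.3, factor_sd = 0.2, seed = 7) {
  if (!is_count(n_genes, min = 2)) stop("`n_genes` must be >= 2",
                                        call. = FALSE)
  if (!is_count(n_stages, min = 3)) stop("`n_stages` must be >= 3",
                                         call. = FALSE)
  if (!is_count(replicates_per_stage, min = 2)) {
    stop("`replicates_per_stage` must be >= 2", call. = FALSE)
  }
  if (!is_number(endpoint_coherence) || endpoint_coherence <= 0 ||
      endpoint_coherence > 1) {
    stop("`endpoint_coherence` must lie in (0, 1]", call. = FALSE)
  }
  if (!is_number(transient_coherence) || transient_coherence < 0 ||
      transient_coherence >= endpoint_coherence) {
    stop("`transient_coherence` must lie in [0, endpoint_coherence)",
         call. = FALSE)
  }
  if (!is_count(n_modules) || n_modules > n_genes) {
    stop("`n_modules` must be a positive integer <= n_genes", call. = FALSE)
  }
  if (!is_number(switch_fraction) || switch_fraction < 0 ||
      switch_fraction > 1) {
    stop("`switch_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is_number(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (!is_number(factor_sd) || factor_sd <= 0) {
    stop("`factor_sd` must be positive", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_stages = n_stages,
                 replicates_per_stage = replicates_per_stage,
                 endpoint_coherence = endpoint_coherence,
                 transient_coherence = transient_coherence,
                 n_modules = n_modules, switch_fraction = switch_fraction,
                 noise_sd = noise_sd, factor_sd = factor_sd,
                 seed = as.integer(seed)),
            class = "arc_design")
}

#' @export
print.arc_design <- function(x, ...) {
  cat(sprintf(paste0("Arc design: %d genes in %d modules, %d stages x %d ",
                     "replicates\n  coherence %.2f (endpoints) / %.2f ",
                     "(transient), switch fraction %.2f, noise sd %.2f, ",
                     "seed %d\n"),
              x$n_genes, x$n_modules, x$n_stages, x$replicates_per_stage,
              x$endpoint_coherence, x$transient_coherence,
              x$switch_fraction, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic arc-shaped differentiation time course
#'
#' Genes are partitioned into near-equal modules; each module has a latent
#' factor drawn per sample as `1 + factor_sd * N(0, 1)`. The expression of
#' gene `g` in sample `s` is
#' `sign(module(g), stage(s)) * coherence(stage(s)) * factor + N(0, noise_sd)`,
#' with coherence equal to `endpoint_coherence` at the first and last stage
#' and `transient_coherence` in between. The first
#' `round(switch_fraction * n_modules)` modules carry sign `+1` over the
#' first half of the stages and `-1` over the second half; their genes are
#' the ground-truth switched set. Deterministic given the design seed.
#'
#' @param design an [arc_design()].
#' @return list with `expression` (genes x samples matrix), `annotation`
#'   (a [stage_annotation()]), `switched_genes` (character), `modules`
#'   (named integer gene -> module map), and the `design`.
#' @export
simulate_arc_dataset <- function(design) {
  if (!inherits(design, "arc_design")) {
    stop("`design` must be created by arc_design()", call. = FALSE)
  }
  d <- design
  set.seed(d$seed)
  n_samples <- d$n_stages * d$replicates_per_stage
  stage_labels <- sprintf("S%d", seq_len(d$n_stages))
  stage_of <- rep(seq_len(d$n_stages), each = d$replicates_per_stage)
  sample_ids <- sprintf("%s_r%02d", stage_labels[stage_of],
                        rep(seq_len(d$replicates_per_stage), d$n_stages))
  gene_ids <- sprintf("g%04d", seq_len(d$n_genes))
  module_of <- sort(rep_len(seq_len(d$n_modules), d$n_genes))
  names(module_of) <- gene_ids

  n_flip <- round(d$switch_fraction * d$n_modules)
  flipped <- seq_len(d$n_modules) <= n_flip
  # stage sign per module: flipped modules are +1 over the first half of
  # the stages and -1 afterwards; others stay +1 throughout
  half <- floor(d$n_stages / 2)
  sign_ms <- matrix(1, d$n_modules, d$n_stages)
  sign_ms[flipped, (half + 1):d$n_stages] <- -1
  coh <- rep(d$transient_coherence, d$n_stages)
  coh[c(1, d$n_stages)] <- d$endpoint_coherence

  factors <- 1 + d$factor_sd * matrix(stats::rnorm(d$n_modules * n_samples),
                                      d$n_modules, n_samples)
  amp <- sign_ms[, stage_of, drop = FALSE] *
    rep(coh[stage_of], each = d$n_modules) # module x sample amplitude
  signal <- (amp * factors)[module_of, , drop = FALSE]
  x <- signal + matrix(stats::rnorm(d$n_genes * n_samples, sd = d$noise_sd),
                       d$n_genes, n_samples)
  dimnames(x) <- list(gene_ids, sample_ids)

  ann <- stage_annotation(sample_ids, stage_labels[stage_of],
                          stage_order = stage_labels)
  list(expression = x, annotation = ann,
       switched_genes = gene_ids[flipped[module_of]],
       modules = module_of, design = d)
}

#' Generate a matched null dataset
#'
#' I.i.d. uniform `[-1, +1]` entries of the requested dimensions: no
#' co-variation structure at all, so network energies fluctuate around
#' zero. Used for false-positive checks and as the perturbation baseline's
#' reference distribution.
#'
#' @param n_genes,n_samples dimensions.
#' @param seed integer seed.
#' @param ann optional [stage_annotation()] supplying sample identifiers.
#' @return genes x samples matrix.
#' @export
simulate_null_dataset <- function(n_genes, n_samples, seed, ann = NULL) {
  if (!is_count(n_genes, min = 2) || !is_count(n_samples, min = 2)) {
    stop("`n_genes` and `n_samples` must be integers >= 2", call. = FALSE)
  }
  sample_ids <- if (!is.null(ann)) {
    if (nrow(ann) != n_samples) {
      stop("`ann` must annotate exactly `n_samples` samples", call. = FALSE)
    }
    ann$sample_id
  } else {
    sprintf("s%03d", seq_len(n_samples))
  }
  set.seed(as.integer(seed))
  x <- matrix(stats::runif(n_genes * n_samples, -1, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sample_ids))
  x
}
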