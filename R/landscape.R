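#' Project samples onto the first two principal components
#'
#' Fits a PCA with samples as observations and genes as features, keeping
#' the two leading components as landscape coordinates. To make results
#' reproducible across linear-algebra backends, each component's loading
#' vector is oriented so that its largest-magnitude entry is positive.
#'
#' @param x numeric genes x samples matrix (z-scored, feature-selected).
#' @return a `pca_projection`: list with `scores` (samples x 2), `rotation`
#'   (genes x 2), `center` (gene means), and `sdev`.
#' @export
project_samples <- function(x) {
  check_expression_matrix(x)
  if (ncol(x) < 3) stop("need >=3 samples for a PCA projection",
                        call. = FALSE)
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2)
  rot <- p$rotation
  scr <- p$x
  if (ncol(rot) < 2) { # rank-deficient data: pad with a zero component
    pad <- 2 - ncol(rot)
    rot <- cbind(rot, matrix(0, nrow(rot), pad))
    scr <- cbind(scr, matrix(0, nrow(scr), pad))
  }
  for (j in 1:2) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) {
      rot[, j] <- -rot[, j]
      scr[, j] <- -scr[, j]
    }
  }
  colnames(rot) <- colnames(scr) <- c("PC1", "PC2")
  rownames(scr) <- colnames(x)
  structure(list(scores = scr, rotation = rot, center = p$center,
                 sdev = p$sdev),
            class = "pca_projection")
}

#' Map low-dimensional coordinates back to expression space
#'
#' Inverse of the linear PCA map fitted by [project_samples()]: a point
#' `(pc1, pc2)` is sent to `point %*% t(rotation) + center`, the
#' reconstruction using only the two retained components.
#'
#' @param proj a `pca_projection`.
#' @param points numeric matrix (m x 2) of PC coordinates.
#' @return an m x genes matrix of reconstructed expression profiles.
#' @export
inverse_project <- function(proj, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  rec <- points %*% t(proj$rotation)
  sweep(rec, 2, proj$center, "+")
}

#' Render the Hopfield energy landscape surface
#'
#' The landscape lives in `n + 1` dimensions (n genes plus energy); to
#' visualise it, a regular grid is laid over the PC1/PC2 bounding box of
#' the samples (expanded by `margin` per side), each grid point is
#' inverse-mapped to expression space, discretised with the *same*
#' threshold as the samples (energy is defined on ternary states), and
#' scored with the Hopfield energy. Each real sample carries its own
#' coordinates and energy.
#'
#' @param x numeric genes x samples matrix (z-scored, feature-selected).
#' @param W weight matrix over the same genes.
#' @param threshold discretisation threshold used for samples and grid.
#' @param grid_size number of grid points per axis (default 50).
#' @param ann optional [stage_annotation()]; adds stages to the sample
#'   points and a stage-centroid trajectory.
#' @param margin fractional bounding-box expansion per side (default 0.1).
#' @return a `hopfield_landscape`: list with `grid_x`, `grid_y`,
#'   `grid_energy` (grid_size x grid_size, `[i, j]` scored at
#'   `(grid_x[i], grid_y[j])`), `samples` (data frame: sample_id, pc1, pc2,
#'   energy, stage), `trajectory` (stage centroids, if `ann` given),
#'   `projection`, and the parameters used.
#' @export
render_surface <- function(x, W, threshold = 0.5, grid_size = 50,
                           ann = NULL, margin = 0.1) {
  if (!is_count(grid_size, min = 2)) {
    stop("`grid_size` must be an integer >= 2", call. = FALSE)
  }
  if (!is_number(margin) || margin < 0) {
    stop("`margin` must be a non-negative number", call. = FALSE)
  }
  if (nrow(x) != nrow(W)) {
    stop("matrix and weight matrix disagree on gene count", call. = FALSE)
  }
  proj <- project_samples(x)
  scr <- proj$scores
  rng_x <- range(scr[, 1])
  rng_y <- range(scr[, 2])
  rng_x <- expand_range(rng_x, margin, "PC1")
  rng_y <- expand_range(rng_y, margin, "PC2")
  grid_x <- seq(rng_x[1], rng_x[2], length.out = grid_size)
  grid_y <- seq(rng_y[1], rng_y[2], length.out = grid_size)

  pts <- cbind(rep(grid_x, times = grid_size),
               rep(grid_y, each = grid_size))
  rec <- t(inverse_project(proj, pts)) # genes x points
  rownames(rec) <- rownames(x)
  colnames(rec) <- sprintf("gp%06d", seq_len(ncol(rec)))
  grid_states <- discretize(rec, threshold)
  ge <- hopfield_energy(grid_states, W)
  grid_energy <- matrix(ge, nrow = grid_size, ncol = grid_size)

  sample_states <- discretize(x, threshold)
  se <- hopfield_energy(sample_states, W)
  stage <- if (!is.null(ann)) {
    validate_annotation(ann, x)
    as.character(ann$stage[match(colnames(x), ann$sample_id)])
  } else {
    NA_character_
  }
  samples <- data.frame(sample_id = colnames(x),
                        pc1 = scr[, 1], pc2 = scr[, 2],
                        energy = unname(se), stage = stage,
                        stringsAsFactors = FALSE, row.names = NULL)
  ls <- structure(list(grid_x = grid_x, grid_y = grid_y,
                       grid_energy = grid_energy, samples = samples,
                       projection = proj,
                       params = list(threshold = threshold,
                                     grid_size = grid_size,
                                     margin = margin,
                                     grid_discretised = TRUE)),
                  class = "hopfield_landscape")
  if (!is.null(ann)) {
    ls$trajectory <- stage_trajectory(samples, stage_order(ann))
  }
  ls
}

expand_range <- function(rng, margin, axis) {
  span <- diff(rng)
  if (span <= 1e-9 * max(1, abs(rng))) {
    warning(sprintf("zero-extent %s axis; expanding by unit margin", axis),
            call. = FALSE)
    return(rng + c(-1, 1))
  }
  rng + c(-1, 1) * margin * span
}

#' Stage-centroid trajectory across the landscape
#'
#' The inferred developmental trajectory: a polyline through the per-stage
#' centroids (mean PC1, mean PC2, mean energy), in stage order.
#'
#' @param samples a `hopfield_landscape`, or its `samples` data frame
#'   (columns pc1, pc2, energy, stage).
#' @param stages stage order; defaults to first appearance.
#' @return data frame with one row per stage: stage, pc1, pc2, energy.
#' @export
stage_trajectory <- function(samples, stages = NULL) {
  if (inherits(samples, "hopfield_landscape")) samples <- samples$samples
  if (any(is.na(samples$stage))) {
    stop("samples carry no stage labels; pass `ann` to render_surface()",
         call. = FALSE)
  }
  stages <- stages %||% unique(samples$stage)
  out <- do.call(rbind, lapply(stages, function(sg) {
    sub <- samples[samples$stage == sg, , drop = FALSE]
    data.frame(stage = sg, pc1 = mean(sub$pc1), pc2 = mean(sub$pc2),
               energy = mean(sub$energy), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.hopfield_landscape <- function(x, ...) {
  cat(sprintf("Hopfield energy landscape: %d x %d grid, %d samples\n",
              length(x$grid_x), length(x$grid_y), nrow(x$samples)))
  cat(sprintf("  energy range on grid: [%.3f, %.3f]\n",
              min(x$grid_energy), max(x$grid_energy)))
  invisible(x)
}

#' Plot a Hopfield energy landscape
#'
#' Two companion views: a 3-D perspective surface (`type = "persp"`) and a
#' top view of the energy field with sample positions and the stage
#' trajectory (`type = "top"`).
#'
#' @param x a `hopfield_landscape`.
#' @param type `"persp"` or `"top"`.
#' @param theta,phi viewing angles for the perspective plot.
#' @param ... further arguments passed to [graphics::persp()] or
#'   [graphics::image()].
#' @export
plot.hopfield_landscape <- function(x, type = c("persp", "top"),
                                    theta = 40, phi = 25, ...) {
  type <- match.arg(type)
  pal <- grDevices::terrain.colors(64)
  if (type == "persp") {
    zi <- cut(x$grid_energy[-1, -1], 64, labels = FALSE)
    graphics::persp(x$grid_x, x$grid_y, x$grid_energy,
                    theta = theta, phi = phi, expand = 0.6,
                    col = pal[zi], border = NA, ticktype = "detailed",
                    xlab = "PC1", ylab = "PC2", zlab = "energy", ...)
  } else {
    graphics::image(x$grid_x, x$grid_y, x$grid_energy, col = pal,
                    xlab = "PC1", ylab = "PC2", ...)
    graphics::contour(x$grid_x, x$grid_y, x$grid_energy, add = TRUE,
                      drawlabels = FALSE, col = "grey30")
    st <- factor(x$samples$stage)
    graphics::points(x$samples$pc1, x$samples$pc2, pch = 19,
                     col = as.integer(st) + 1)
    if (!is.null(x$trajectory)) {
      graphics::lines(x$trajectory$pc1, x$trajectory$pc2, lwd = 2)
      graphics::points(x$trajectory$pc1, x$trajectory$pc2, pch = 4, lwd = 2)
    }
    if (nlevels(st) > 0 && !anyNA(x$samples$stage)) {
      graphics::legend("topright", legend = levels(st), pch = 19,
                       col = seq_len(nlevels(st)) + 1, bty = "n")
    }
  }
  invisible(x)
}

#' Write a landscape surface as long-format TSV
#'
#' One row per grid point: `pc1`, `pc2`, `energy`.
#'
#' @param landscape a `hopfield_landscape`.
#' @param path output path.
#' @export
write_surface <- function(landscape, path) {
  gs <- length(landscape$grid_x)
  df <- data.frame(pc1 = rep(landscape$grid_x, times = gs),
                   pc2 = rep(landscape$grid_y, each = gs),
                   energy = as.vector(landscape$grid_energy))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a landscape bundle (grid, samples, trajectory, parameters) as JSON
#'
#' The parameter block records the grid resolution and the fact that grid
#' points are discretised before scoring, for transparency.
#'
#' @inheritParams write_surface
#' @export
write_landscape_json <- function(landscape, path) {
  jsonlite::write_json(
    list(grid_x = landscape$grid_x, grid_y = landscape$grid_y,
         grid_energy = landscape$grid_energy,
         samples = landscape$samples,
         trajectory = landscape$trajectory,
         params = landscape$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
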