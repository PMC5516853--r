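test_that("identical samples project to the origin", {
  x <- matrix(1:6, 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  proj <- project_samples(x)
  expect_equal(unname(proj$scores), matrix(0, 4, 2), tolerance = 1e-12)
  expect_error(project_samples(tiny_matrix(4, 2)), ">=3 samples")
})

test_that("projection followed by inverse projection recovers rank-2 data", {
  # construct data lying exactly in a 2-D affine subspace
  set.seed(11)
  load <- matrix(rnorm(12), 6, 2)
  scores <- matrix(rnorm(16), 8, 2) %*% diag(c(3, 1))
  x <- t(scores %*% t(load)) + rnorm(6)
  dimnames(x) <- list(paste0("g", 1:6), paste0("s", 1:8))
  proj <- project_samples(x)
  rec <- inverse_project(proj, proj$scores)
  expect_equal(unname(rec), unname(t(x)), tolerance = 1e-8)
})

test_that("variance concentrated on one gene separates clusters along PC1", {
  x <- rbind(g1 = c(-5, -5, -5, 5, 5, 5),
             g2 = c(0.1, -0.1, 0, 0.05, -0.05, 0))
  colnames(x) <- paste0("s", 1:6)
  proj <- project_samples(x)
  pc1 <- proj$scores[, 1]
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) ||
                min(pc1[1:3]) > max(pc1[4:6]))
  # loading sign convention: dominant entry positive
  expect_true(proj$rotation[which.max(abs(proj$rotation[, 1])), 1] > 0)
})

test_that("surface grid spans the sample bounding box plus margin", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls <- render_surface(as$z, W, grid_size = 12, ann = as$ann, margin = 0.1)
  expect_true(all(is.finite(ls$grid_energy)))
  expect_lte(min(ls$grid_x), min(ls$samples$pc1))
  expect_gte(max(ls$grid_x), max(ls$samples$pc1))
  expect_lte(min(ls$grid_y), min(ls$samples$pc2))
  expect_gte(max(ls$grid_y), max(ls$samples$pc2))
  expect_identical(dim(ls$grid_energy), c(12L, 12L))
  # sample points carry their own energies
  se <- hopfield_energy(as$states, W)
  expect_equal(ls$samples$energy, unname(se[ls$samples$sample_id]),
               tolerance = 1e-12)
})

test_that("an in-plane grid point scores the same energy as the sample", {
  # rank-2 data: every sample lies exactly in the PC1-PC2 plane, so the
  # inverse map reproduces it. The latent scores are symmetric about the
  # origin, so with margin 0 and an odd grid the central grid point
  # coincides exactly with the (0, 0) sample.
  set.seed(3)
  load <- matrix(rnorm(20), 10, 2)
  sc <- rbind(c(-2, -1), c(2, -1), c(-2, 1), c(2, 1), c(0, 0))
  x <- t(sc %*% t(load))
  dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:5))
  W <- build_weight_matrix(x)
  ls <- render_surface(x, W, threshold = 0.5, grid_size = 5, margin = 0)
  expect_equal(ls$samples$pc1[5], 0, tolerance = 1e-9)
  expect_equal(ls$grid_x[3], 0, tolerance = 1e-9)
  expect_equal(ls$grid_energy[3, 3], ls$samples$energy[5], tolerance = 1e-9)
})

test_that("degenerate axes are expanded with a warning", {
  x <- rbind(g1 = c(-3, 0, 3, -3, 0, 3),
             g2 = c(-6, 0, 6, -6, 0, 6))
  colnames(x) <- paste0("s", 1:6)
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("g1", "g2")))
  expect_warning(ls <- render_surface(x, W, grid_size = 4), "zero-extent")
  expect_gt(diff(range(ls$grid_y)), 1)
})

test_that("grid refinement preserves energies at coinciding coordinates", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls3 <- render_surface(as$z, W, grid_size = 3, ann = as$ann)
  ls5 <- render_surface(as$z, W, grid_size = 5, ann = as$ann)
  # sizes 3 and 5 share the corner and centre coordinates
  expect_equal(ls3$grid_x[c(1, 2, 3)], ls5$grid_x[c(1, 3, 5)],
               tolerance = 1e-12)
  expect_equal(ls3$grid_energy[c(1, 2, 3), c(1, 2, 3)],
               ls5$grid_energy[c(1, 3, 5), c(1, 3, 5)],
               tolerance = 1e-12)
  # deterministic re-render
  ls3b <- render_surface(as$z, W, grid_size = 3, ann = as$ann)
  expect_identical(ls3$grid_energy, ls3b$grid_energy)
})

test_that("the stage trajectory is an ordered polyline of centroids", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls <- render_surface(as$z, W, grid_size = 8, ann = as$ann)
  tr <- ls$trajectory
  expect_identical(tr$stage, stage_order(as$ann))
  sg <- stage_order(as$ann)[2]
  sub <- ls$samples[ls$samples$stage == sg, ]
  expect_equal(tr$pc1[2], mean(sub$pc1), tolerance = 1e-12)
  expect_equal(tr$energy[2], mean(sub$energy), tolerance = 1e-12)

  # singleton stages give their sample's coordinates; 2 stages = 1 segment
  x <- tiny_matrix(5, 4)
  ann <- stage_annotation(colnames(x), c("A", "A", "A", "B"))
  Wx <- build_weight_matrix(x)
  ls2 <- render_surface(x, Wx, grid_size = 4, ann = ann)
  expect_identical(nrow(ls2$trajectory), 2L)
  expect_equal(ls2$trajectory$pc1[2],
               ls2$samples$pc1[ls2$samples$stage == "B"], tolerance = 1e-12)
})

test_that("the trajectory energy rises then falls across the arc", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls <- render_surface(as$z, W, grid_size = 15, ann = as$ann)
  e <- ls$trajectory$energy
  k <- length(e)
  expect_true(which.max(e) %in% 2:(k - 1))
  expect_true(max(e[c(1, k)]) < min(e[2:(k - 1)]))
})

test_that("surface energy is higher near transient-stage samples", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls <- render_surface(as$z, W, grid_size = 25, ann = as$ann)
  # neighbourhood = nearest 4 grid points of each sample
  neigh_energy <- function(px, py) {
    ix <- order(abs(ls$grid_x - px))[1:2]
    iy <- order(abs(ls$grid_y - py))[1:2]
    mean(ls$grid_energy[ix, iy])
  }
  ne <- mapply(neigh_energy, ls$samples$pc1, ls$samples$pc2)
  so <- stage_order(as$ann)
  endpoint <- ls$samples$stage %in% so[c(1, length(so))]
  expect_gt(mean(ne[!endpoint]), mean(ne[endpoint]))
})

test_that("surfaces export as long-format TSV", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  ls <- render_surface(as$z, W, grid_size = 6, ann = as$ann)
  path <- tempfile(fileext = ".tsv")
  write_surface(ls, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 36L)
  hit <- which(abs(tab$pc1 - ls$grid_x[2]) < 1e-9 &
                 abs(tab$pc2 - ls$grid_y[3]) < 1e-9)
  expect_equal(tab$energy[hit], ls$grid_energy[2, 3], tolerance = 1e-9)
})
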