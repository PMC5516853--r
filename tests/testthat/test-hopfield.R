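test_that("weight matrix is symmetric, zero-diagonal, correlation-valued", {
  x <- tiny_matrix(5, 6)
  x["g02", ] <- x["g01", ]      # duplicate
  x["g03", ] <- -x["g01", ]     # negation
  W <- build_weight_matrix(x)
  expect_identical(W, t(W))
  expect_identical(unname(diag(W)), rep(0, 5))
  expect_true(all(abs(W) <= 1 + 1e-12))
  expect_equal(W["g01", "g02"], 1, tolerance = 1e-12)
  expect_equal(W["g01", "g03"], -1, tolerance = 1e-12)
})

test_that("weight matrix preconditions are enforced", {
  x <- tiny_matrix(4, 5)
  x["g03", ] <- 2
  expect_error(build_weight_matrix(x), "g03")
  expect_error(build_weight_matrix(tiny_matrix(4, 2)), ">=3 samples")
  expect_error(build_weight_matrix(tiny_matrix(1, 5)), ">=2 genes")
})

test_that("energy matches hand-worked examples", {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(hopfield_energy(c(a = 1, b = 1), w), -1)
  expect_equal(hopfield_energy(c(a = 1, b = -1), w), 1)
  expect_equal(hopfield_energy(c(a = 0, b = 0), w), 0)
  expect_error(hopfield_energy(c(1, 1, 1), w), "mismatch")
})

test_that("matrix-form energy equals the brute-force double loop", {
  for (seed in 1:50) {
    inst <- random_instance(sample(2:12, 1), seed)
    expect_equal(hopfield_energy(inst$H, inst$W),
                 brute_force_energy(inst$H, inst$W), tolerance = 1e-9)
  }
})

test_that("energy respects sign and permutation symmetry", {
  for (seed in 1:10) {
    inst <- random_instance(8, seed)
    e <- hopfield_energy(inst$H, inst$W)
    expect_equal(hopfield_energy(-inst$H, inst$W), e, tolerance = 1e-12)
    set.seed(seed + 1000)
    p <- sample(8)
    expect_equal(hopfield_energy(inst$H[p], inst$W[p, p]), e,
                 tolerance = 1e-12)
  }
})

test_that("stage energies average per-sample energies within stages", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  pr <- stage_energies(as$states, W, as$ann)
  expect_named(pr$per_stage, stage_order(as$ann))
  for (sg in stage_order(as$ann)) {
    ids <- as$ann$sample_id[as$ann$stage == sg]
    expect_equal(unname(pr$per_stage[sg]), mean(pr$per_sample[ids]),
                 tolerance = 1e-12)
  }

  # one sample per stage: per-stage equals per-sample verbatim
  x <- tiny_matrix(5, 4)
  ann1 <- stage_annotation(colnames(x), paste0("T", 1:4))
  W1 <- build_weight_matrix(x)
  pr1 <- stage_energies(discretize(x, 0.5), W1, ann1)
  expect_equal(unname(pr1$per_stage), unname(pr1$per_sample),
               tolerance = 1e-12)

  # duplicating a sample's state within a stage leaves the mean unchanged
  st <- discretize(x, 0.5)
  st2 <- cbind(st, dup = st[, 1])
  ann2 <- stage_annotation(colnames(st2), c("T1", "T2", "T3", "T4", "T1"),
                           stage_order = paste0("T", 1:4))
  pr2 <- stage_energies(st2, W1, ann2)
  expect_equal(pr2$per_stage["T1"], pr1$per_stage["T1"], tolerance = 1e-12)
})

test_that("centroid stage energies score the consensus state", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  pr <- stage_energies(as$states, W, as$ann, stage_method = "centroid")
  sg <- stage_order(as$ann)[1]
  expect_equal(unname(pr$per_stage[sg]),
               hopfield_energy(stage_consensus(as$states, as$ann, sg), W),
               tolerance = 1e-12)
})

test_that("transient stages sit higher in energy than endpoints", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  e <- stage_energies(as$states, W, as$ann)$per_stage
  k <- length(e)
  expect_true(max(e[c(1, k)]) < min(e[2:(k - 1)]))
})

test_that("recall returns fixed points unchanged with trajectory length 1", {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- hopfield_recall(c(a = 1L, b = 1L), w)
  expect_identical(res$state, c(a = 1L, b = 1L))
  expect_identical(length(res$trajectory), 1L)
  expect_true(res$converged)
  expect_equal(res$trajectory, -1)
})

test_that("recall reaches a global minimum of the 2-node network", {
  # enumeration oracle over all 9 ternary states
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  grid <- expand.grid(a = -1:1, b = -1:1)
  energies <- apply(grid, 1, function(h) brute_force_energy(h, w))
  minima <- grid[energies == min(energies), ]
  expect_identical(min(energies), -1)
  expect_identical(nrow(minima), 2L) # (+1,+1) and (-1,-1)

  res <- hopfield_recall(c(a = 1L, b = -1L), w)
  expect_equal(unname(res$state[1]), unname(res$state[2]))
  expect_true(abs(res$state[1]) == 1)
  expect_equal(res$trajectory[length(res$trajectory)], -1)
})

test_that("asynchronous recall never increases the energy", {
  for (seed in 1:30) {
    inst <- random_instance(sample(3:10, 1), seed + 400)
    res <- hopfield_recall(inst$H, inst$W, max_sweeps = 50)
    expect_true(all(diff(res$trajectory) <= 1e-12))
    expect_true(res$trajectory[1] <= hopfield_energy(inst$H, inst$W) + 1e-12)
  }
})

test_that("energy profiles round-trip through TSV and JSON", {
  sim <- small_arc()
  as <- arc_states(sim)
  W <- build_weight_matrix(as$z)
  pr <- stage_energies(as$states, W, as$ann)
  tsv <- tempfile(fileext = ".tsv")
  write_energy_profile(pr, tsv, "tsv")
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), ncol(as$states))
  expect_equal(tab$energy, unname(pr$per_sample[tab$sample_id]),
               tolerance = 1e-12)
  js <- tempfile(fileext = ".json")
  write_energy_profile(pr, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(unlist(parsed$per_stage), pr$per_stage, tolerance = 1e-12)
})
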