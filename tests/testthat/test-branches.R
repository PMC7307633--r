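test_that("toy tree decomposes into the known branches", {
  bt <- decompose_branches(toy_tree())
  expect_equal(nrow(bt), 3L)
  expect_setequal(bt$kind, c("stem", "tip", "tip"))
  expect_equal(sort(bt$length), c(50, 50, 50))
  expect_equal(sum(bt$length), 150)
  expect_true(all(bt$compartment == "apical"))
  expect_equal(sum(bt$is_terminal), 2L)
})

test_that("morphometry_summary reports the toy tree exactly", {
  s <- morphometry_summary(toy_tree())
  expect_equal(s$apical$NB, 3L)
  expect_equal(s$apical$TDBL, 150)
  expect_equal(s$apical$mean_BL, 50)
  expect_equal(s$apical$n_stems, 1L)
  expect_equal(s$apical$n_tips, 2L)
  expect_equal(s$apical$n_intermediate, 0L)
  expect_equal(s$apical$NB_excl_stems, 2L)
  expect_equal(s$basal$NB, 0L)
  expect_true(is.na(s$basal$mean_BL))
})

test_that("branch lengths sum to the edge-sum oracle on generated trees", {
  coh <- gen_morphology_cohort(morph_cohort_spec(), 8, seed = 42)
  for (m in coh$cells) {
    bt <- decompose_branches(m)
    expect_equal(sum(bt$length), edge_sum_tdbl(m), tolerance = 1e-9)
  }
})

test_that("branch statistics are invariant to rigid motions", {
  m <- gen_morphology_cohort(morph_cohort_spec(), 1, seed = 7)$cells[[1]]
  bt <- decompose_branches(m)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  n2 <- m$nodes
  xy <- as.matrix(n2[, c("x", "y")]) %*% t(R)
  n2$x <- xy[, 1] + 123; n2$y <- xy[, 2] - 45; n2$z <- n2$z + 9
  bt2 <- decompose_branches(neuron_morphology(n2))
  expect_equal(bt2$length, bt$length, tolerance = 1e-9)
  expect_equal(bt2$kind, bt$kind)
  expect_equal(bt2$midpoint_distance, bt$midpoint_distance, tolerance = 1e-9)
})

test_that("inserting a degree-2 node changes no branch statistic", {
  m <- toy_tree()
  # subdivide the edge 1 -> 2 with a collinear midpoint node
  n <- rbind(m$nodes,
             data.frame(id = 5L, type = 4L, x = 0, y = 25, z = 0,
                        radius = 1, parent = 1L))
  n$parent[n$id == 2L] <- 5L
  # reorder parents-before-children: 1, 5, 2, 3, 4
  n <- n[match(c(1L, 5L, 2L, 3L, 4L), n$id), ]
  bt0 <- decompose_branches(m)
  bt1 <- decompose_branches(neuron_morphology(n))
  expect_equal(nrow(bt1), nrow(bt0))
  expect_equal(sort(bt1$length), sort(bt0$length), tolerance = 1e-9)
  expect_equal(sort(bt1$kind), sort(bt0$kind))
})

test_that("a trifurcation starts three daughter branches", {
  m <- neuron_morphology(data.frame(
    id = 1:5, type = c(1L, 4L, 4L, 4L, 4L),
    x = c(0, 0, -10, 0, 10), y = c(0, 10, 20, 20, 20), z = 0,
    radius = 1, parent = c(-1L, 1L, 2L, 2L, 2L)))
  bt <- decompose_branches(m)
  expect_equal(nrow(bt), 4L)
  expect_equal(sum(bt$kind == "tip"), 3L)
})

test_that("dendrites attached to non-dendritic nodes are rejected", {
  expect_error(decompose_branches(neuron_morphology(data.frame(
    id = 1:3, type = c(1L, 2L, 4L), x = 0, y = c(0, 1, 2), z = 0,
    radius = 1, parent = c(-1L, 1L, 2L)))),
    "attaches to non-dendritic node")
})

test_that("density profiles integrate to one", {
  s <- morphometry_summary(
    gen_morphology_cohort(morph_cohort_spec(), 1, seed = 3)$cells[[1]])
  prof <- s$apical$density_profile
  expect_false(is.null(prof))
  expect_equal(sum(prof$density) * prof$step, 1, tolerance = 1e-9)
  expect_error(morphometry_summary(toy_tree(), gridstep = 10),
               "must be <= 5")
})

test_that("apical terminations are classified against layer geometry", {
  g <- flat_geometry()
  # tips at y = -100 (L1A), y = -30 (L1B); soma deep of the L1b/L2a border
  m <- neuron_morphology(data.frame(
    id = 1:4, type = c(1L, 4L, 4L, 4L),
    x = c(0, 0, 0, 30), y = c(60, 0, -100, -30), z = 0,
    radius = 1, parent = c(-1L, 1L, 2L, 2L)))
  s <- morphometry_summary(m, geometry = g)
  expect_equal(s$per_layer$L1A$n, 1L)
  expect_equal(s$per_layer$L1B$n, 1L)
  # stem terminates exactly on the L1b/L2a border -> deeper layer, L2
  expect_equal(s$per_layer$L2$n, 1L)
})
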