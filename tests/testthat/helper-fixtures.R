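# Shared fixtures: hand-constructed toy trees with known morphometrics
# and a brute-force TDBL oracle.

# Toy neuron: soma at origin; apical stem to (0,50,0) that bifurcates into
# tips at (0,100,0) and (50,50,0). NB = 3 (1 stem + 2 tips), every branch
# 50 um, TDBL = 150 um.
toy_tree <- function(metadata = list()) {
  neuron_morphology(data.frame(
    id = 1:4, type = c(1L, 4L, 4L, 4L),
    x = c(0, 0, 0, 50), y = c(0, 50, 100, 50), z = 0,
    radius = c(5, 1, 1, 1), parent = c(-1L, 1L, 2L, 2L)),
    metadata = metadata)
}

# Minimal cell with one apical and one basal branch of chosen length,
# for cohort-level tests.
toy_cell <- function(depth_norm, basal_len, age_group = "grp") {
  neuron_morphology(data.frame(
    id = 1:3, type = c(1L, 4L, 3L),
    x = 0, y = c(0, -50, basal_len), z = 0,
    radius = c(5, 1, 1), parent = c(-1L, 1L, 1L)),
    metadata = list(age_group = age_group, cell_class = "L2B",
                    depth_norm = depth_norm))
}

# Brute-force TDBL oracle: sum of child-to-parent Euclidean distances over
# all dendritic nodes (type 3/4), independent of the branch decomposition.
edge_sum_tdbl <- function(m) {
  n <- m$nodes
  dend <- n$type %in% c(3L, 4L)
  idx <- match(n$parent, n$id)
  sum(sqrt((n$x[dend] - n$x[idx[dend]])^2 +
           (n$y[dend] - n$y[idx[dend]])^2 +
           (n$z[dend] - n$z[idx[dend]])^2))
}

# Three parallel horizontal boundaries: L1a/L1b at y = -60, L1b/L2a at
# y = 0, L2/L3 at y = 120 (layer 2 width 120 um, depth increases with +y).
flat_geometry <- function() {
  layer_geometry(
    l1a_l1b = cbind(c(-100, 100), -60),
    l1b_l2a = cbind(c(-100, 100), 0),
    l2_l3 = cbind(c(-100, 100), 120))
}
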