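# Branch decomposition and morphometry.
#
# A branch runs from a soma attachment or a bifurcation to the next
# bifurcation or terminal point; unbranched chains of degree-2 nodes belong
# to one branch. Branch kinds follow the field's counting convention:
# a stem leaves the soma (and is one branch in its own right), a tip ends
# in a terminal point, an intermediate ends in a bifurcation. NB (number of
# branches) = stems + intermediates + tips.

#' Decompose a morphology into dendritic branches
#'
#' Splits the apical and basal dendritic trees into branches delimited by
#' soma attachments, bifurcations (multifurcations allowed: k children
#' start k daughter branches) and terminal points. Branch length is the sum
#' of 3-D Euclidean inter-node segment lengths, including the segment from
#' the anchoring soma/bifurcation node to the branch's first node.
#'
#' @param m a [neuron_morphology()].
#' @return A data.frame (class `branch_table`) with one row per branch:
#'   `branch_id`, `compartment` ("apical"/"basal"), `kind`
#'   ("stem"/"intermediate"/"tip"), `is_terminal`, `length` (um),
#'   `n_nodes`, `distal_x/y/z`, `midpoint_distance` (um, soma centroid to
#'   the branch's arc-length midpoint) and `termination_layer`
#'   (`NA` until classified against a [layer_geometry()]). The per-branch
#'   node-id paths (anchor node first) are kept in `attr(, "node_paths")`.
#' @examples
#' m <- neuron_morphology(data.frame(
#'   id = 1:4, type = c(1, 4, 4, 4),
#'   x = c(0, 0, 0, 50), y = c(0, 50, 100, 50), z = 0,
#'   radius = 1, parent = c(-1, 1, 2, 2)))
#' decompose_branches(m)
#' @export
decompose_branches <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  nodes <- m$nodes
  idx <- setNames(seq_len(nrow(nodes)), nodes$id)
  dend <- nodes$type %in% c(SWC_BASAL, SWC_APICAL)
  soma <- nodes$type == SWC_SOMA

  # dendritic children of each node
  kids <- split(nodes$id[dend & nodes$parent != -1L],
                factor(nodes$parent[dend & nodes$parent != -1L],
                       levels = nodes$id))
  n_kids <- lengths(kids)

  # sanity: every dendritic node must hang off the soma or another dendrite
  for (i in which(dend)) {
    p <- nodes$parent[i]
    if (p == -1L)
      stop(sprintf("dendritic node %d is the tree root (isolated dendrite)",
                   nodes$id[i]), call. = FALSE)
    pt <- nodes$type[idx[[as.character(p)]]]
    if (!(pt %in% c(SWC_SOMA, SWC_BASAL, SWC_APICAL)))
      stop(sprintf("dendritic node %d attaches to non-dendritic node %d",
                   nodes$id[i], p), call. = FALSE)
  }

  # branch starts: dendritic nodes whose parent is soma or a branch point
  starts <- integer(0)
  for (i in which(dend)) {
    p_id <- as.character(nodes$parent[i])
    p_row <- idx[[p_id]]
    if (soma[p_row] || n_kids[[p_id]] >= 2L) starts <- c(starts, nodes$id[i])
  }

  paths <- list()
  rows <- list()
  bid <- 0L
  for (s in starts) {
    bid <- bid + 1L
    path <- s
    cur <- s
    repeat {
      ch <- kids[[as.character(cur)]]
      if (length(ch) != 1L) break
      cur <- ch
      path <- c(path, cur)
    }
    anchor <- nodes$parent[idx[[as.character(s)]]]
    full <- c(anchor, path)
    pts <- as.matrix(nodes[idx[as.character(full)], c("x", "y", "z")])
    seglen <- sqrt(rowSums(diff(pts)^2))
    len <- sum(seglen)
    distal <- pts[nrow(pts), ]
    is_stem <- soma[idx[[as.character(anchor)]]]
    terminal <- length(kids[[as.character(cur)]]) == 0L
    kind <- if (is_stem) "stem" else if (terminal) "tip" else "intermediate"
    mid <- .arc_midpoint(pts, seglen)
    paths[[bid]] <- full
    rows[[bid]] <- data.frame(
      branch_id = bid,
      compartment = if (nodes$type[idx[[as.character(s)]]] == SWC_APICAL)
        "apical" else "basal",
      kind = kind, is_terminal = terminal, length = len,
      n_nodes = length(path),
      distal_x = distal[1], distal_y = distal[2], distal_z = distal[3],
      midpoint_distance = .euclid(mid, m$soma_centroid),
      termination_layer = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch_id = integer(0), compartment = character(0),
               kind = character(0), is_terminal = logical(0),
               length = numeric(0), n_nodes = integer(0),
               distal_x = numeric(0), distal_y = numeric(0),
               distal_z = numeric(0), midpoint_distance = numeric(0),
               termination_layer = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "node_paths") <- paths
  class(out) <- c("branch_table", "data.frame")
  out
}

# point at half the arc length along a polyline (rows = points)
.arc_midpoint <- function(pts, seglen = sqrt(rowSums(diff(pts)^2))) {
  total <- sum(seglen)
  if (total == 0) return(pts[1L, ])
  target <- total / 2
  cum <- cumsum(seglen)
  k <- which(cum >= target)[1L]
  excess <- cum[k] - target
  frac <- if (seglen[k] > 0) 1 - excess / seglen[k] else 0
  pts[k, ] + frac * (pts[k + 1L, ] - pts[k, ])
}

# Gaussian KDE on a fixed grid, renormalised so sum(y) * step == 1.
# Silverman's rule (bw.nrd0); falls back to a 5-um bandwidth when the
# sample is degenerate (n < 2 or zero spread).
.kde_profile <- function(values, gridstep = 2, fallback_bw = 5) {
  if (length(values) == 0L) return(NULL)
  bw <- if (length(values) >= 2L && stats::sd(values) > 0)
    stats::bw.nrd0(values) else fallback_bw
  lo <- max(0, min(values) - 3 * bw)
  hi <- max(values) + 3 * bw
  grid <- seq(lo, hi, by = gridstep)
  if (length(grid) < 2L) grid <- c(lo, lo + gridstep)
  d <- stats::density(values, bw = bw, from = grid[1L],
                      to = grid[length(grid)], n = length(grid))
  y <- d$y / (sum(d$y) * gridstep)
  list(distance = d$x, density = y, bw = bw, step = gridstep)
}

.empty_compartment_summary <- function() {
  list(NB = 0L, TDBL = 0, n_stems = 0L, n_tips = 0L, n_intermediate = 0L,
       NB_excl_stems = 0L, mean_BL = NA_real_, branch_lengths = numeric(0),
       density_profile = NULL)
}

.compartment_summary <- function(br, gridstep) {
  if (nrow(br) == 0L) return(.empty_compartment_summary())
  nb <- nrow(br)
  tdbl <- sum(br$length)
  list(
    NB = nb,
    TDBL = tdbl,
    n_stems = sum(br$kind == "stem"),
    n_tips = sum(br$kind == "tip"),
    n_intermediate = sum(br$kind == "intermediate"),
    NB_excl_stems = nb - sum(br$kind == "stem"),
    mean_BL = tdbl / nb,
    branch_lengths = br$length,
    density_profile = .kde_profile(br$midpoint_distance, gridstep))
}

#' Morphometric summary of one reconstruction
#'
#' Computes, per dendritic compartment, the branch count NB, total
#' dendritic branch length (TDBL, um), stem/intermediate/tip counts, mean
#' branch length, the raw branch-length vector and a kernel-density profile
#' of branch midpoint Euclidean distances from the soma (Gaussian kernel,
#' Silverman bandwidth, grid step <= 5 um, normalised to unit mass).
#' Because the field reports branch numbers both with and without the stem
#' segments, `NB` (stems counted) and `NB_excl_stems` are both returned.
#'
#' When a [layer_geometry()] is supplied, apical branches are additionally
#' classified by termination layer ([classify_termination_layer()]) and
#' per-layer sub-summaries (branch count, TDBL, mean BL, branch-length
#' density) are included.
#'
#' @param m a [neuron_morphology()].
#' @param geometry optional [layer_geometry()].
#' @param gridstep density grid step in um (<= 5).
#' @return An object of class `morphometry_summary`: lists `apical` and
#'   `basal` (fields above), `per_layer` (or `NULL`), `branches` (the
#'   branch table) and `metadata`.
#' @export
morphometry_summary <- function(m, geometry = NULL, gridstep = 2) {
  stopifnot(inherits(m, "neuron_morphology"))
  if (gridstep > 5) stop("`gridstep` must be <= 5 um", call. = FALSE)
  br <- decompose_branches(m)
  if (!is.null(geometry)) {
    ap <- br$compartment == "apical"
    if (any(ap)) {
      cls <- vapply(which(ap), function(i)
        classify_termination_layer(
          c(br$distal_x[i], br$distal_y[i]), geometry)$layer, character(1))
      br$termination_layer[ap] <- cls
    }
  }
  per_layer <- NULL
  if (!is.null(geometry)) {
    per_layer <- lapply(c(L1A = "L1A", L1B = "L1B", L2 = "L2"), function(L) {
      sub <- br[br$compartment == "apical" &
                  !is.na(br$termination_layer) & br$termination_layer == L, ]
      list(n = nrow(sub), TDBL = sum(sub$length),
           mean_BL = if (nrow(sub)) mean(sub$length) else NA_real_,
           branch_length_density = .kde_profile(sub$length, gridstep))
    })
  }
  structure(
    list(apical = .compartment_summary(br[br$compartment == "apical", ], gridstep),
         basal = .compartment_summary(br[br$compartment == "basal", ], gridstep),
         per_layer = per_layer, branches = br, metadata = m$metadata),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  fmt <- function(s, name)
    cat(sprintf("  %-6s NB %3d (stems %d, interm %d, tips %d)  TDBL %8.1f um  mean BL %s\n",
                name, s$NB, s$n_stems, s$n_intermediate, s$n_tips, s$TDBL,
                if (is.na(s$mean_BL)) "-" else sprintf("%.1f um", s$mean_BL)))
  cat("<morphometry_summary>\n")
  fmt(x$apical, "apical"); fmt(x$basal, "basal")
  if (!is.null(x$per_layer)) {
    counts <- vapply(x$per_layer, `[[`, 0, "n")
    cat(sprintf("  apical terminations: L1A %d / L1B %d / L2 %d\n",
                counts[["L1A"]], counts[["L1B"]], counts[["L2"]]))
  }
  invisible(x)
}
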