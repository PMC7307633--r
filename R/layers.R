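# Laminar geometry: traced boundary polylines and layer assignment.
#
# The aPCx slice plane is treated as x-y; three ordered boundary polylines
# delimit the compartments (superficial to deep): L1a/L1b, L1b/L2a, L2/L3.
# The depth axis orientation says along which coordinate depth increases.

#' Laminar boundary geometry
#'
#' @param l1a_l1b,l1b_l2a,l2_l3 two-column matrices/data.frames of ordered
#'   (x, y) vertices (um) tracing each boundary, superficial to deep:
#'   L1a/L1b, L1b/L2a (the layer-2 upper border) and L2/L3.
#' @param depth_axis direction of increasing cortical depth: `"+y"`
#'   (default), `"-y"`, `"+x"` or `"-x"`.
#' @return Object of class `layer_geometry`.
#' @export
layer_geometry <- function(l1a_l1b, l1b_l2a, l2_l3, depth_axis = "+y") {
  depth_axis <- match.arg(depth_axis, c("+y", "-y", "+x", "-x"))
  as_poly <- function(p, name) {
    p <- as.matrix(as.data.frame(p)[, 1:2])
    colnames(p) <- c("x", "y")
    if (nrow(p) < 2L)
      stop(sprintf("boundary %s needs at least 2 vertices", name), call. = FALSE)
    storage.mode(p) <- "double"
    p
  }
  g <- structure(list(l1a_l1b = as_poly(l1a_l1b, "L1a/L1b"),
                      l1b_l2a = as_poly(l1b_l2a, "L1b/L2a"),
                      l2_l3 = as_poly(l2_l3, "L2/L3"),
                      depth_axis = depth_axis),
                 class = "layer_geometry")
  # boundaries must be ordered along the depth axis (L1a/L1b most superficial)
  d <- vapply(g[1:3], function(p) mean(.to_depth_frame(p, depth_axis)[, 2]), 0)
  if (is.unsorted(d, strictly = TRUE))
    stop("boundaries are not ordered superficial to deep along the depth axis",
         call. = FALSE)
  g
}

# rotate coordinates so that depth increases along column 2 ("d"),
# lateral position along column 1 ("l")
.to_depth_frame <- function(pts, depth_axis) {
  pts <- rbind(pts)  # ensure matrix, accepts a bare c(x, y)
  out <- switch(depth_axis,
    "+y" = pts[, c(1, 2), drop = FALSE],
    "-y" = cbind(pts[, 1], -pts[, 2]),
    "+x" = pts[, c(2, 1), drop = FALSE],
    "-x" = cbind(pts[, 2], -pts[, 1]))
  colnames(out) <- c("l", "d")
  out
}

#' Read laminar boundaries from a polyline CSV
#'
#' Expects columns `boundary` (names containing `l1a_l1b` / `l1b_l2a` /
#' `l2_l3`, case-insensitive, `/` and `-` treated as `_`), `vertex`
#' (ordering index), `x`, `y`.
#'
#' @param path CSV path.
#' @param depth_axis see [layer_geometry()].
#' @return A `layer_geometry`.
#' @export
read_layer_geometry <- function(path, depth_axis = "+y") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("boundary", "vertex", "x", "y")
  if (!all(need %in% names(df)))
    stop("layer geometry CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- tolower(gsub("[/\\-]", "_", df$boundary))
  pick <- function(tag) {
    sub <- df[grepl(tag, key), ]
    if (nrow(sub) == 0L) stop("boundary ", tag, " missing from ", path,
                              call. = FALSE)
    sub <- sub[order(sub$vertex), ]
    as.matrix(sub[, c("x", "y")])
  }
  layer_geometry(pick("l1a_l1b"), pick("l1b_l2a"), pick("l2_l3"), depth_axis)
}

#' Write laminar boundaries to a polyline CSV
#' @param g a `layer_geometry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_layer_geometry <- function(g, path) {
  stopifnot(inherits(g, "layer_geometry"))
  rows <- lapply(c("l1a_l1b", "l1b_l2a", "l2_l3"), function(nm) {
    p <- g[[nm]]
    data.frame(boundary = nm, vertex = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# nearest point on a polyline: returns distance, point, segment index
.polyline_nearest <- function(p, poly) {
  p <- as.numeric(p[1:2])
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
    pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  d2 <- (p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2
  k <- which.min(d2)
  list(distance = unname(sqrt(d2[k])), point = unname(proj[k, ]),
       segment = k)
}

# boundary depth at a given lateral coordinate, in the depth frame;
# extrapolates with the nearest end segment outside the traced extent
.boundary_depth_at <- function(poly_df, lateral) {
  l <- poly_df[, "l"]; d <- poly_df[, "d"]
  o <- order(l)
  l <- l[o]; d <- d[o]
  extrapolated <- lateral < min(l) || lateral > max(l)
  if (length(unique(l)) < 2L)
    return(list(depth = mean(d), extrapolated = extrapolated))
  res <- stats::approx(l, d, xout = lateral, rule = 1, ties = mean)$y
  if (is.na(res)) {  # outside extent: extend nearest segment linearly
    if (lateral < l[1L]) {
      sl <- (d[2L] - d[1L]) / (l[2L] - l[1L])
      res <- d[1L] + sl * (lateral - l[1L])
    } else {
      n <- length(l)
      sl <- (d[n] - d[n - 1L]) / (l[n] - l[n - 1L])
      res <- d[n] + sl * (lateral - l[n])
    }
  }
  list(depth = res, extrapolated = extrapolated)
}

#' Classify a point into cortical layer L1A / L1B / L2
#'
#' Determines which laminar compartment contains a point (typically a
#' branch termination) from its position relative to the traced L1a/L1b
#' and L1b/L2a boundaries. Points exactly on a boundary are assigned to the
#' deeper layer; points outside the traced lateral extent are classified
#' against the nearest-segment linear extension and flagged.
#'
#' @param point numeric (x, y) position in slice coordinates (um); a 3-D
#'   point is accepted, z is ignored.
#' @param g a [layer_geometry()].
#' @return list with `layer` ("L1A", "L1B" or "L2") and `extrapolated`.
#' @export
classify_termination_layer <- function(point, g) {
  stopifnot(inherits(g, "layer_geometry"))
  pf <- .to_depth_frame(as.numeric(point[1:2]), g$depth_axis)
  b1 <- .boundary_depth_at(.to_depth_frame(g$l1a_l1b, g$depth_axis), pf[1, "l"])
  b2 <- .boundary_depth_at(.to_depth_frame(g$l1b_l2a, g$depth_axis), pf[1, "l"])
  depth <- pf[1, "d"]
  layer <- if (depth < b1$depth) "L1A" else if (depth < b2$depth) "L1B" else "L2"
  list(layer = layer, extrapolated = b1$extrapolated || b2$extrapolated)
}

#' Normalised soma depth in layer 2 and cell classification
#'
#' The position of a cell in layer 2 is the smallest Euclidean distance
#' from the soma to the L1b/L2a boundary, normalised to the local width of
#' layer 2, measured along the perpendicular through the soma from the
#' L1b/L2a boundary to the L2/L3 boundary. Cells in the superficial third
#' (`depth_norm < 1/3`) are class L2A; deeper cells (ties included) are
#' L2B. A soma superficial to the L1b/L2a boundary yields a negative
#' `depth_norm` with a warning and an unassigned class.
#'
#' @param soma numeric (x, y) soma position (um); z ignored if present.
#' @param g a [layer_geometry()].
#' @return list with `depth_norm`, `cell_class` ("L2A"/"L2B"/`NA`),
#'   `layer2_width` (um) and `extrapolated`.
#' @export
normalized_depth <- function(soma, g) {
  stopifnot(inherits(g, "layer_geometry"))
  p <- as.numeric(soma[1:2])
  near <- .polyline_nearest(p, g$l1b_l2a)
  dist <- near$distance

  # side of the boundary: compare depth-frame coordinates
  pf <- .to_depth_frame(p, g$depth_axis)
  b2 <- .boundary_depth_at(.to_depth_frame(g$l1b_l2a, g$depth_axis), pf[1, "l"])
  superficial <- pf[1, "d"] < b2$depth

  # direction of the perpendicular through the soma
  u <- if (dist > 0) (p - near$point) / dist else {
    # soma exactly on the boundary: use the depth axis direction
    switch(g$depth_axis, "+y" = c(0, 1), "-y" = c(0, -1),
           "+x" = c(1, 0), "-x" = c(-1, 0))
  }
  if (superficial) u <- -u
  ray <- .ray_polyline_intersect(near$point, u, g$l2_l3)
  width <- ray$t
  if (!is.finite(width) || width <= 0)
    stop("cannot measure layer-2 width: perpendicular through the soma does ",
         "not reach the L2/L3 boundary", call. = FALSE)
  depth_norm <- (if (superficial) -dist else dist) / width
  if (superficial) {
    warning("soma lies superficial to the L1b/L2a boundary; depth_norm < 0 ",
            "and cell class unassigned")
    cls <- NA_character_
  } else {
    cls <- if (depth_norm < 1 / 3) "L2A" else "L2B"
  }
  list(depth_norm = unname(depth_norm), cell_class = cls,
       layer2_width = unname(width), extrapolated = ray$extrapolated)
}

# first intersection of ray origin + t*u (t > 0) with a polyline; if the
# ray misses the traced extent, the nearest end segment is extended
.ray_polyline_intersect <- function(origin, u, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    hit <- .ray_segment_t(origin, u, a[i, ], b[i, ], clamp = TRUE)
    if (!is.na(hit) && hit > 0 && hit < best) best <- hit
  }
  if (is.finite(best)) return(list(t = best, extrapolated = FALSE))
  # extend the segment whose line the ray crosses nearest
  best <- Inf
  for (i in seq_len(nrow(a))) {
    hit <- .ray_segment_t(origin, u, a[i, ], b[i, ], clamp = FALSE)
    if (!is.na(hit) && hit > 0 && hit < best) best <- hit
  }
  list(t = best, extrapolated = TRUE)
}

# parameter t where origin + t*u crosses the (optionally clamped) segment ab
.ray_segment_t <- function(origin, u, a, b, clamp = TRUE) {
  v <- b - a
  den <- u[1] * (-v[2]) - u[2] * (-v[1])
  if (abs(den) < 1e-12) return(NA_real_)
  w <- a - origin
  t <- (w[1] * (-v[2]) - w[2] * (-v[1])) / den
  s <- (u[1] * w[2] - u[2] * w[1]) / den
  if (clamp && (s < 0 || s > 1)) return(NA_real_)
  t
}
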