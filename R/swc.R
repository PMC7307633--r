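# SWC reconstruction I/O and the neuron_morphology container.
#
# SWC is the standard 7-column plain-text format for neuronal
# reconstructions: id, type, x, y, z, radius, parent (parent = -1 for the
# root). Type codes follow the usual convention: 1 = soma, 3 = basal
# dendrite, 4 = apical dendrite; other codes are preserved but ignored by
# the morphometry.

SWC_SOMA   <- 1L
SWC_BASAL  <- 3L
SWC_APICAL <- 4L

#' Construct a neuron morphology from an SWC node table
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (one row per SWC node, parents before children).
#' @param metadata optional named list of cell-level metadata (e.g.
#'   `age_group`, `depth_norm`, `cell_class`).
#' @return An object of class `neuron_morphology`: the validated node table
#'   plus `soma_centroid` (mean position of soma nodes, falling back to the
#'   root) and `metadata`.
#' @seealso [read_swc()], [decompose_branches()]
#' @export
neuron_morphology <- function(nodes, metadata = list()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    stop("`nodes` must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  .validate_swc_nodes(nodes)
  soma_rows <- nodes$type == SWC_SOMA
  soma_centroid <- if (any(soma_rows)) {
    colMeans(nodes[soma_rows, c("x", "y", "z")])
  } else {
    unlist(nodes[nodes$parent == -1L, c("x", "y", "z")][1L, ])
  }
  structure(
    list(nodes = nodes, soma_centroid = as.numeric(soma_centroid),
         metadata = metadata),
    class = "neuron_morphology"
  )
}

# Structural validation shared by the constructor and the parser.
# `lines` maps node rows to source line numbers for error messages.
.validate_swc_nodes <- function(nodes, lines = seq_len(nrow(nodes))) {
  if (nrow(nodes) == 0L) stop("SWC node table is empty", call. = FALSE)
  dup <- duplicated(nodes$id)
  if (any(dup))
    stop(sprintf("duplicate node id %d (line %d)",
                 nodes$id[dup][1L], lines[dup][1L]), call. = FALSE)
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L)
    stop("no root node (parent = -1) found", call. = FALSE)
  if (length(roots) > 1L)
    stop(sprintf("multiple roots: node %d (line %d) is a second root",
                 nodes$id[roots[2L]], lines[roots[2L]]), call. = FALSE)
  # parents must already have appeared: catches dangling references and,
  # together with id uniqueness, rules out cycles and disconnection
  seen <- integer(0)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (p != -1L) {
      if (p == nodes$id[i])
        stop(sprintf("node %d is its own parent (cycle, line %d)",
                     nodes$id[i], lines[i]), call. = FALSE)
      if (!(p %in% seen))
        stop(sprintf(
          "node %d (line %d) references parent %d which does not appear earlier",
          nodes$id[i], lines[i], p), call. = FALSE)
    }
    seen <- c(seen, nodes$id[i])
  }
  invisible(TRUE)
}

#' Read an SWC reconstruction file
#'
#' Parses a 7-column SWC file (comment lines start with `#`) into a
#' [neuron_morphology()]. Structural defects — duplicate ids, dangling or
#' forward parent references, multiple roots — raise an error naming the
#' offending line.
#'
#' @param path path to an SWC file.
#' @param metadata optional metadata list passed through to the morphology.
#' @return A `neuron_morphology`.
#' @examples
#' swc <- tempfile(fileext = ".swc")
#' writeLines(c("# toy", "1 1 0 0 0 5 -1", "2 4 0 50 0 1 1"), swc)
#' m <- read_swc(swc)
#' nrow(m$nodes)
#' @export
read_swc <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  body <- raw[keep]
  lines <- which(keep)
  if (length(body) == 0L) stop("no SWC records in ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop(sprintf("line %d of %s does not have 7 columns", lines[bad[1L]], path),
         call. = FALSE)
  mat <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(mat))
    stop("non-numeric field in SWC body of ", path, call. = FALSE)
  nodes <- data.frame(id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
                      x = mat[, 3], y = mat[, 4], z = mat[, 5],
                      radius = mat[, 6], parent = as.integer(mat[, 7]))
  .validate_swc_nodes(nodes, lines)
  neuron_morphology(nodes, metadata)
}

#' Write a morphology back to SWC
#'
#' @param m a `neuron_morphology`.
#' @param path output file path.
#' @param digits significant digits for coordinates and radii.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path, digits = 6) {
  stopifnot(inherits(m, "neuron_morphology"))
  n <- m$nodes
  num <- function(v) formatC(v, digits = digits, format = "g")
  out <- paste(n$id, n$type, num(n$x), num(n$y), num(n$z), num(n$radius),
               n$parent)
  writeLines(c("# generated by apcdend", out), path)
  invisible(path)
}

#' @export
print.neuron_morphology <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<neuron_morphology> %d nodes (%d soma, %d basal, %d apical)\n",
              nrow(n), sum(n$type == SWC_SOMA), sum(n$type == SWC_BASAL),
              sum(n$type == SWC_APICAL)))
  cat(sprintf("  soma centroid: (%.1f, %.1f, %.1f) um\n",
              x$soma_centroid[1], x$soma_centroid[2], x$soma_centroid[3]))
  if (length(x$metadata))
    cat("  metadata: ", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
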