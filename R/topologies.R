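#' @name topologies
#' @title Cage topology graphs
#'
#' @description
#' A cage topology is a connected graph whose vertices are building blocks
#' (typed by arity 2, 3 or 4) and whose edges are the inter-building-block
#' bonds. Each vertex carries an ideal unit position used to seed assembly:
#' positions are centred on the origin with unit circumradius, and scaling
#' to bead dimensions happens at assembly time. The registry ships the named
#' topologies used throughout (`TriXDiY` notation: X tritopic + Y ditopic
#' blocks; subscript variants such as `Tri4_2Di6` are alternative graphs at
#' the same stoichiometry).
NULL

.topology_registry <- new.env(parent = emptyenv())

new_topology <- function(name, vertices, edges) {
  g <- structure(
    list(name = name, vertices = vertices, edges = edges,
         n_building_blocks = nrow(vertices)),
    class = "topology_graph"
  )
  bad <- validate_graph(g)
  if (length(bad) > 0) {
    abort(paste0("invalid topology '", name, "': ", paste(bad, collapse = "; ")))
  }
  g
}

#' @exportS3Method base::print
print.topology_graph <- function(x, ...) {
  comp <- table(x$vertices$arity)
  cat(sprintf("<topology %s> %d vertices (%s), %d edges\n",
              x$name, nrow(x$vertices),
              paste(sprintf("%s of arity %s", comp, names(comp)), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

vertex_tbl <- function(arity, pos) {
  tibble(id = seq_len(nrow(pos)), arity = as.integer(arity),
         x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

edge_tbl <- function(v1, v2) {
  tibble(edge = seq_along(v1), v1 = as.integer(v1), v2 = as.integer(v2))
}

# --- reference polyhedra (unit circumradius, centred) -----------------------

poly_tetrahedron <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

poly_octahedron <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

poly_cube <- function() {
  as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))) / sqrt(3)
}

poly_cuboctahedron <- function() {
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  m <- rbind(
    cbind(s[, 1], s[, 2], 0),
    cbind(s[, 1], 0, s[, 2]),
    cbind(0, s[, 1], s[, 2])
  )
  colnames(m) <- NULL
  m / sqrt(2)
}

# equilateral trigonal prism (triangle side = height), unit circumradius
poly_trigonal_prism <- function() {
  s <- 1
  r <- s / sqrt(3)
  az <- deg2rad(c(90, 210, 330))
  top <- cbind(r * cos(az), r * sin(az), s / 2)
  m <- rbind(top, cbind(top[, 1:2], -s / 2))
  m / sqrt(r^2 + s^2 / 4)
}

# square antiprism with all edges equal, unit circumradius
poly_square_antiprism <- function() {
  s <- 1
  r <- s / sqrt(2)
  # lateral edge^2 = 2 r^2 (1 - cos 45) + h^2 = s^2 -> h^2 = s^2 (1 - (2 - sqrt(2)) / 2)
  h2 <- s^2 * (1 - (2 - sqrt(2)) / 2)
  h <- sqrt(h2)
  az_top <- deg2rad(c(0, 90, 180, 270))
  az_bot <- deg2rad(c(45, 135, 225, 315))
  m <- rbind(
    cbind(r * cos(az_top), r * sin(az_top), h / 2),
    cbind(r * cos(az_bot), r * sin(az_bot), -h / 2)
  )
  m / sqrt(r^2 + h2 / 4)
}

# edges of a polyhedron = vertex pairs at the minimal pairwise distance
poly_edges <- function(pos, tol = 1e-6) {
  d <- as.matrix(stats::dist(pos))
  dmin <- min(d[d > tol])
  which(d <= dmin + tol & upper.tri(d), arr.ind = TRUE)
}

# polyhedron vertices (arity k) + one ditopic vertex on each edge midpoint
midpoint_topology <- function(name, pos, arity) {
  e <- poly_edges(pos)
  mids <- (pos[e[, 1], , drop = FALSE] + pos[e[, 2], , drop = FALSE]) / 2
  nv <- nrow(pos)
  vertices <- vertex_tbl(c(rep(arity, nv), rep(2L, nrow(e))),
                         rbind(pos, mids))
  v1 <- c(e[, 1], e[, 2])
  v2 <- rep(nv + seq_len(nrow(e)), 2)
  new_topology(name, vertices, edge_tbl(v1, v2))
}

# two k-arity poles bridged by k equatorial ditopics
prism_pair_topology <- function(name, arity) {
  k <- arity
  az <- deg2rad(seq(0, 360, length.out = k + 1)[seq_len(k)])
  pos <- rbind(c(0, 0, 1), c(0, 0, -1), cbind(cos(az), sin(az), 0))
  vertices <- vertex_tbl(c(k, k, rep(2L, k)), pos)
  di <- 2L + seq_len(k)
  new_topology(name, vertices, edge_tbl(c(rep(1L, k), rep(2L, k)), c(di, di)))
}

# tetrahedron of polytopic blocks with a mix of single and double ditopic
# bridges; `double` lists the doubled base-edge pairs
bridged_tetrahedron_topology <- function(name, arity, single, double,
                                         offset = 0.35) {
  pos <- poly_tetrahedron()
  di_pos <- list(); v1 <- integer(); v2 <- integer()
  add_di <- function(a, b, shift) {
    mid <- (pos[a, ] + pos[b, ]) / 2 + shift
    di_pos[[length(di_pos) + 1]] <<- mid
    di <- 4L + length(di_pos)
    v1 <<- c(v1, a, b); v2 <<- c(v2, di, di)
  }
  for (p in single) add_di(p[1], p[2], c(0, 0, 0))
  for (p in double) {
    axis <- pos[p[2], ] - pos[p[1], ]
    mid <- (pos[p[1], ] + pos[p[2], ]) / 2
    perp <- pracma_cross(axis, if (sqrt(sum(mid^2)) > 1e-6) mid else c(0, 0, 1))
    perp <- unit(perp) * offset
    add_di(p[1], p[2], perp)
    add_di(p[1], p[2], -perp)
  }
  vertices <- vertex_tbl(c(rep(arity, 4), rep(2L, length(di_pos))),
                         rbind(pos, do.call(rbind, di_pos)))
  new_topology(name, vertices, edge_tbl(v1, v2))
}

tet6tri8_topology <- function() {
  oct <- poly_octahedron()
  cub <- poly_cube()
  v1 <- integer(); v2 <- integer()
  for (i in seq_len(8)) {
    corner <- cub[i, ]
    for (j in seq_len(6)) {
      if (sum(oct[j, ] * corner) > 0.5) { # the 3 axis-aligned neighbours
        v1 <- c(v1, j); v2 <- c(v2, 6L + i)
      }
    }
  }
  vertices <- vertex_tbl(c(rep(4L, 6), rep(3L, 8)), rbind(oct, cub))
  new_topology("Tet6Tri8", vertices, edge_tbl(v1, v2))
}

build_default_registry <- function() {
  list(
    Tri2Di3 = prism_pair_topology("Tri2Di3", 3L),
    Tri4Di6 = midpoint_topology("Tri4Di6", poly_tetrahedron(), 3L),
    Tri4_2Di6 = bridged_tetrahedron_topology(
      "Tri4_2Di6", 3L,
      single = list(c(1, 3), c(2, 4)),
      double = list(c(1, 2), c(3, 4))
    ),
    Tri6Di9 = midpoint_topology("Tri6Di9", poly_trigonal_prism(), 3L),
    Tri8Di12 = midpoint_topology("Tri8Di12", poly_cube(), 3L),
    Tet2Di4 = prism_pair_topology("Tet2Di4", 4L),
    Tet4_2Di8 = bridged_tetrahedron_topology(
      "Tet4_2Di8", 4L,
      single = list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
      double = list(c(1, 2), c(3, 4))
    ),
    Tet6Di12 = midpoint_topology("Tet6Di12", poly_octahedron(), 4L),
    Tet8Di16 = midpoint_topology("Tet8Di16", poly_square_antiprism(), 4L),
    Tet12Di24 = midpoint_topology("Tet12Di24", poly_cuboctahedron(), 4L),
    Tet6Tri8 = tet6tri8_topology()
  )
}

ensure_registry <- function() {
  if (!length(ls(.topology_registry))) {
    for (g in build_default_registry()) {
      assign(g$name, g, envir = .topology_registry)
    }
  }
}

#' Look up a named cage topology
#'
#' @param name topology name, e.g. `"Tri4Di6"`; see [list_topologies()].
#' @return a validated `topology_graph`.
#' @examples
#' get_topology("Tri4Di6")
#' @export
get_topology <- function(name) {
  ensure_registry()
  if (!exists(name, envir = .topology_registry, inherits = FALSE)) {
    abort(paste0("unknown topology '", name, "'. Available: ",
                 paste(sort(ls(.topology_registry)), collapse = ", ")))
  }
  get(name, envir = .topology_registry, inherits = FALSE)
}

#' Register a custom topology graph
#'
#' @param vertices tibble with columns `id`, `arity`, `x`, `y`, `z`
#'   (unit-scale ideal positions).
#' @param edges tibble with columns `v1`, `v2` (vertex ids); an `edge` id
#'   column is added if absent.
#' @param name topology name.
#' @return the registered `topology_graph`, invisibly.
#' @export
register_topology <- function(name, vertices, edges) {
  ensure_registry()
  if (!"edge" %in% names(edges)) edges$edge <- seq_len(nrow(edges))
  g <- new_topology(name, as_tibble(vertices),
                    as_tibble(edges)[, c("edge", "v1", "v2")])
  assign(name, g, envir = .topology_registry)
  invisible(g)
}

#' List registered topologies
#'
#' @return a tibble with `name`, `composition` (counts by arity) and
#'   `n_building_blocks`, sorted by name.
#' @export
list_topologies <- function() {
  ensure_registry()
  nms <- sort(ls(.topology_registry))
  purrr::map_dfr(nms, function(nm) {
    g <- get_topology(nm)
    comp <- table(g$vertices$arity)
    tibble(
      name = nm,
      composition = paste(sprintf("%dx%sC", as.integer(comp), names(comp)),
                          collapse = " + "),
      n_building_blocks = g$n_building_blocks
    )
  })
}

#' Validate a topology graph
#'
#' Checks that every vertex degree equals its arity, the handshake identity
#' holds, the graph is connected, and no 2-arity vertex binds the same
#' partner twice.
#'
#' @param g a `topology_graph` (or a bare list with the same fields).
#' @return a character vector of violations; empty when valid.
#' @export
validate_graph <- function(g) {
  out <- character()
  deg <- tabulate(c(g$edges$v1, g$edges$v2), nbins = nrow(g$vertices))
  bad <- which(deg != g$vertices$arity)
  if (length(bad) > 0) {
    out <- c(out, paste0("degree != arity at vertex ", paste(bad, collapse = ",")))
  }
  if (sum(g$vertices$arity) != 2 * nrow(g$edges)) {
    out <- c(out, "handshake violation: sum(arity) != 2 * n_edges")
  }
  # connectivity via sparse adjacency power iteration
  n <- nrow(g$vertices)
  adj <- Matrix::sparseMatrix(i = c(g$edges$v1, g$edges$v2),
                              j = c(g$edges$v2, g$edges$v1),
                              x = 1, dims = c(n, n))
  reach <- rep(FALSE, n); reach[1] <- TRUE
  repeat {
    new <- as.logical(adj %*% reach > 0) | reach
    if (identical(new, reach)) break
    reach <- new
  }
  if (!all(reach)) out <- c(out, "graph is not connected")
  two <- g$vertices$id[g$vertices$arity == 2]
  for (v in two) {
    partners <- c(g$edges$v2[g$edges$v1 == v], g$edges$v1[g$edges$v2 == v])
    if (anyDuplicated(partners)) {
      out <- c(out, paste0("ditopic vertex ", v, " binds a partner twice"))
    }
  }
  out
}

#' Pairwise angles between ideal edge directions at a vertex
#'
#' For a vertex of the ideal (unit-scale) topology template, returns the
#' angles between the unit vectors pointing toward each connected neighbour,
#' over all neighbour pairs.
#'
#' @param name topology name.
#' @param vertex vertex id.
#' @return numeric vector of angles in degrees, sorted increasing.
#' @examples
#' ideal_vertex_angles("Tri6Di9", 1) # 60, 90, 90
#' @export
ideal_vertex_angles <- function(name, vertex) {
  g <- get_topology(name)
  if (!vertex %in% g$vertices$id) abort(paste0("unknown vertex ", vertex))
  pos <- as.matrix(g$vertices[, c("x", "y", "z")])
  partners <- c(g$edges$v2[g$edges$v1 == vertex], g$edges$v1[g$edges$v2 == vertex])
  if (length(partners) < 2) abort("vertex must have arity >= 2")
  dirs <- t(vapply(partners, function(p) unit(pos[p, ] - pos[vertex, ]),
                   numeric(3)))
  pairs <- combn(length(partners), 2)
  ang <- apply(pairs, 2, function(ij) {
    ct <- sum(dirs[ij[1], ] * dirs[ij[2], ])
    rad2deg(acos(pmin(1, pmax(-1, ct))))
  })
  sort(ang)
}
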