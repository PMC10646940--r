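#' @name shape_measures
#' @title Continuous shape measures and pore radius
#'
#' @description
#' The continuous shape measure (CShM) quantifies the deviation of an
#' n-point set from an ideal reference polyhedron on a dimensionless 0-100
#' scale: 0 means the set is similar (rotation + isotropic scale +
#' translation) to the reference, and the minimum is taken over all vertex
#' labellings. Cage shapes are measured on building-block centroids, e.g.
#' the six tetratopic centroids of an octahedral cage against OC-6.
NULL

shape_defs <- function() {
  list(
    "TP-3" = {
      az <- deg2rad(c(90, 210, 330))
      cbind(cos(az), sin(az), 0)
    },
    "T-4" = poly_tetrahedron(),
    "SP-4" = {
      az <- deg2rad(c(0, 90, 180, 270))
      cbind(cos(az), sin(az), 0)
    },
    "OC-6" = poly_octahedron(),
    "TPR-6" = poly_trigonal_prism(),
    "CU-8" = poly_cube(),
    "SAPR-8" = poly_square_antiprism()
  )
}

#' Reference shape
#'
#' @param label one of `"TP-3"`, `"T-4"`, `"SP-4"`, `"OC-6"`, `"TPR-6"`,
#'   `"CU-8"`, `"SAPR-8"` (vertex count is the suffix). TPR-6 is the
#'   equilateral trigonal prism and SAPR-8 the equal-edge square antiprism.
#' @return a `reference_shape`: label, `n` and centred unit mean-square
#'   radius coordinates.
#' @export
reference_shape <- function(label) {
  defs <- shape_defs()
  if (!label %in% names(defs)) {
    abort(paste0("unknown reference shape '", label, "'. Available: ",
                 paste(names(defs), collapse = ", ")))
  }
  xyz <- defs[[label]]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- xyz / sqrt(mean(rowSums(xyz^2)))
  structure(list(label = label, n = nrow(xyz), xyz = xyz),
            class = "reference_shape")
}

#' List available reference shapes
#' @return character vector of labels.
#' @export
list_reference_shapes <- function() names(shape_defs())

# squared correlation of centred sets p, q under the optimal rotation for a
# fixed vertex matching (rows aligned): (sum of signed singular values)^2
procrustes_score <- function(p, q) {
  s <- svd(t(q) %*% p)
  sv <- s$d
  sv[3] <- sv[3] * sign(det(s$u) * det(s$v))
  sum(sv)^2
}

#' Continuous shape measure
#'
#' `100 * min` over vertex permutation, rotation, translation and isotropic
#' scale of the normalised squared deviation between the point set and the
#' reference. The permutation minimum is exact: depth-first assignment with
#' a radius-product upper bound prunes labellings that cannot beat the
#' current best.
#'
#' @param points n-by-3 matrix of points.
#' @param ref a [reference_shape()] or its label.
#' @return a `shape_measure` list: `measure` (0-100), `permutation` (maps
#'   reference vertex i to point row `permutation[i]`), `label`.
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' cshm(cube, "CU-8")$measure # 0
#' @export
cshm <- function(points, ref) {
  if (is.character(ref)) ref <- reference_shape(ref)
  points <- as.matrix(points)
  if (nrow(points) != ref$n) {
    abort(paste0("point count ", nrow(points), " != reference n ", ref$n))
  }
  p <- sweep(points, 2, colMeans(points))
  pnorm2 <- sum(p^2)
  if (pnorm2 < 1e-20) abort("degenerate point set (zero variance)")
  q <- ref$xyz
  qnorm2 <- sum(q^2)
  n <- ref$n
  rp <- sqrt(rowSums(p^2)) # point radii
  rq <- sqrt(rowSums(q^2)) # reference radii

  best <- list(score = -Inf, perm = seq_len(n))
  assigned <- integer(n)
  used <- logical(n)

  # bound: sum_i |q_i||p_perm(i)| over the unassigned block is at most the
  # descending-order pairing of the remaining radii
  dfs <- function(depth, cov, rad_sum) {
    if (depth > n) {
      sc <- sum({
        s <- svd(cov)
        d <- s$d; d[3] <- d[3] * sign(det(s$u) * det(s$v)); d
      })^2
      if (sc > best$score) best <<- list(score = sc, perm = assigned)
      return(invisible())
    }
    rem_q <- if (depth < n) sort(rq[(depth + 1):n], decreasing = TRUE) else numeric(0)
    for (cand in seq_len(n)) {
      if (used[cand]) next
      rs <- rad_sum + rq[depth] * rp[cand]
      rem_p <- sort(rp[!used & seq_len(n) != cand], decreasing = TRUE)
      ub <- rs + sum(rem_q * rem_p)
      if (best$score > 0 && ub^2 <= best$score) next
      used[cand] <<- TRUE
      assigned[depth] <<- cand
      dfs(depth + 1, cov + q[depth, ] %o% p[cand, ], rs)
      used[cand] <<- FALSE
    }
  }
  dfs(1, matrix(0, 3, 3), 0)

  measure <- 100 * max(0, 1 - best$score / (pnorm2 * qnorm2))
  structure(list(measure = measure, permutation = best$perm,
                 label = ref$label),
            class = "shape_measure")
}

#' @exportS3Method base::print
print.shape_measure <- function(x, ...) {
  cat(sprintf("<shape_measure %s> %.6g\n", x$label, x$measure))
  invisible(x)
}

#' Building-block centroids of a cage
#'
#' Unweighted centroid of each building block's beads, in cage (vertex)
#' order, for the requested block class.
#'
#' @param cage a `cage_model`.
#' @param which `"ditopic"`, `"tritopic"` or `"tetratopic"`.
#' @return m-by-3 matrix of centroids.
#' @export
bb_centroids <- function(cage, which = c("ditopic", "tritopic", "tetratopic")) {
  which <- match.arg(which)
  arity <- switch(which, ditopic = 2L, tritopic = 3L, tetratopic = 4L)
  sel <- cage$beads$arity == arity
  if (!any(sel)) {
    abort(paste0("cage has no ", which, " building blocks"))
  }
  verts <- unique(cage$beads$vertex[sel])
  t(vapply(verts, function(v) {
    colMeans(cage$xyz[cage$beads$vertex == v, , drop = FALSE])
  }, numeric(3)))
}

# topology -> (block class -> reference label); 12-vertex and larger
# centroid sets are skipped to avoid the permutation cost
shape_mapping <- function() {
  list(
    Tri2Di3 = list(ditopic = "TP-3"),
    Tri4Di6 = list(tritopic = "T-4", ditopic = "OC-6"),
    Tri4_2Di6 = list(tritopic = "T-4", ditopic = "OC-6"),
    Tri6Di9 = list(tritopic = "TPR-6"),
    Tri8Di12 = list(tritopic = "CU-8"),
    Tet2Di4 = list(ditopic = "SP-4"),
    Tet4_2Di8 = list(tetratopic = "T-4", ditopic = "CU-8"),
    Tet6Di12 = list(tetratopic = "OC-6"),
    Tet8Di16 = list(tetratopic = "SAPR-8"),
    Tet12Di24 = list(),
    Tet6Tri8 = list(tetratopic = "OC-6", tritopic = "CU-8")
  )
}

#' Shape report for a cage
#'
#' Computes every configured shape measure for the cage's topology (e.g.
#' OC-6 on the six tetratopic centroids of Tet6Di12). Topologies whose
#' centroid sets all exceed 8 vertices have no configured measures.
#'
#' @param cage a `cage_model` or `cage_opt`.
#' @param mapping optional override of the topology-to-shape mapping.
#' @return named numeric vector of measures keyed by reference label;
#'   empty (with a warning) for unmapped topologies.
#' @export
shape_report <- function(cage, mapping = shape_mapping()) {
  if (inherits(cage, "cage_opt")) cage <- cage$cage
  mp <- mapping[[cage$topology]]
  if (is.null(mp)) {
    warn(paste0("no shape mapping configured for topology ", cage$topology))
    return(setNames(numeric(0), character(0)))
  }
  if (length(mp) == 0) return(setNames(numeric(0), character(0)))
  out <- vapply(names(mp), function(cls) {
    cshm(bb_centroids(cage, cls), mp[[cls]])$measure
  }, numeric(1))
  setNames(out, unlist(mp))
}

#' Approximate pore radius
#'
#' Distance from the bead centroid of the cage to the nearest bead surface:
#' `max(0, min_i(|x_i - centroid| - sigma_i / 2))`, in Angstrom.
#'
#' @param cage a `cage_model` or `cage_opt`.
#' @return pore radius in Angstrom (floored at 0).
#' @export
pore_radius <- function(cage) {
  if (inherits(cage, "cage_opt")) cage <- cage$cage
  ctr <- colMeans(cage$xyz)
  d <- sqrt(rowSums(sweep(cage$xyz, 2, ctr)^2))
  max(0, min(d - cage$beads$sigma / 2))
}
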