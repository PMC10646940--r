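#' @name cage_builder
#' @title Assembling cage models from building blocks and a topology
#'
#' @description
#' Assembly places one building block on each topology vertex (rigidly
#' translated to the scaled ideal position and rotated so that its binder
#' directions superpose onto the directions of its incident edges), then
#' forms one inter-building-block bond per topology edge and enumerates the
#' complete force-field term lists: bonds, angles, optional ditopic
#' backbone torsions and the excluded-volume pair list (pairs separated by
#' two or fewer bonds are exempt).
NULL

# Kabsch: rotation R minimising sum |R p_i - q_i|^2 (row vectors)
kabsch_rotation <- function(p, q) {
  s <- svd(t(p) %*% q)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Best rotation mapping binder directions onto edge directions, minimising
# the superposition residual over binder-to-edge assignments. Ties broken
# deterministically by iterating permutations in lexicographic order and
# keeping only strict improvements (lowest-index binder to lowest-index edge).
align_binders <- function(binder_dirs, edge_dirs) {
  k <- nrow(binder_dirs)
  perms <- perm_matrix(k)
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    rot <- kabsch_rotation(binder_dirs, edge_dirs[pm, , drop = FALSE])
    resid <- sum((binder_dirs %*% t(rot) - edge_dirs[pm, , drop = FALSE])^2)
    if (is.null(best) || resid < best$resid - 1e-12) {
      best <- list(rot = rot, perm = pm, resid = resid)
    }
  }
  best
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

block_for_vertex <- function(blocks, vertex_id, arity) {
  if (!is.null(names(blocks)) && as.character(vertex_id) %in% names(blocks)) {
    b <- blocks[[as.character(vertex_id)]]
  } else {
    hit <- which(vapply(blocks, function(b) b$arity == arity, logical(1)))
    if (length(hit) == 0) {
      abort(paste0("no building block of arity ", arity,
                   " supplied for vertex ", vertex_id))
    }
    b <- blocks[[hit[1]]]
  }
  if (b$arity != arity) {
    abort(paste0("arity mismatch at vertex ", vertex_id, ": topology needs ",
                 arity, ", block has ", b$arity))
  }
  b
}

block_extent <- function(block) {
  ctr <- colMeans(block$xyz)
  max(sqrt(rowSums(sweep(block$xyz, 2, ctr)^2)))
}

# smallest deterministic scale: every edge long enough for the two block
# extents plus the new bond, then grown until no inter-block bead clash
assembly_scale <- function(g, blocks_by_vertex, placed_fun, sigma_bar) {
  pos <- as.matrix(g$vertices[, c("x", "y", "z")])
  need <- vapply(seq_len(nrow(g$edges)), function(e) {
    v1 <- g$edges$v1[e]; v2 <- g$edges$v2[e]
    b1 <- blocks_by_vertex[[v1]]; b2 <- blocks_by_vertex[[v2]]
    r0 <- mix_r0(b1$beads$bond_r[b1$binder_idx[1]],
                 b2$beads$bond_r[b2$binder_idx[1]])
    ext <- block_extent(b1) + block_extent(b2) + r0
    gap <- sqrt(sum((pos[v1, ] - pos[v2, ])^2))
    ext / gap
  }, numeric(1))
  scale <- max(need)
  for (iter in 1:50) {
    placed <- placed_fun(scale)
    if (min_cross_block_distance(placed) >= 1.2 * sigma_bar) break
    scale <- scale * 1.1
  }
  scale
}

min_cross_block_distance <- function(placed) {
  xyz <- do.call(rbind, lapply(placed, `[[`, "xyz"))
  owner <- rep(seq_along(placed), vapply(placed, function(p) nrow(p$xyz),
                                         integer(1)))
  d <- as.matrix(stats::dist(xyz))
  same <- outer(owner, owner, "==")
  d[same] <- Inf
  min(d)
}

#' Place building blocks on a topology graph
#'
#' Rigidly positions one building block per vertex: translation to the
#' scaled ideal vertex position and the rotation that best superposes the
#' block's binder directions onto its incident edge directions (optimal
#' orthogonal superposition, assignment chosen over binder permutations).
#'
#' @param g a `topology_graph`.
#' @param blocks a list of `building_block`s. Blocks are matched to
#'   vertices by arity; alternatively a named list keyed by vertex id.
#' @param scale multiplier applied to the unit ideal positions; `NULL`
#'   (default) picks the smallest scale with no initial clash.
#' @return a list with per-vertex placements (`xyz`, rotation, binder-to-edge
#'   assignment) and the resolved `scale`.
#' @export
place_building_blocks <- function(g, blocks, scale = NULL) {
  if (inherits(blocks, "building_block")) blocks <- list(blocks)
  blocks_by_vertex <- lapply(seq_len(nrow(g$vertices)), function(i) {
    block_for_vertex(blocks, g$vertices$id[i], g$vertices$arity[i])
  })
  sigma_bar <- mean(unlist(lapply(blocks_by_vertex,
                                  function(b) b$beads$sigma)))
  pos <- as.matrix(g$vertices[, c("x", "y", "z")])

  place_at <- function(sc) {
    lapply(seq_len(nrow(g$vertices)), function(v) {
      b <- blocks_by_vertex[[v]]
      inc <- which(g$edges$v1 == v | g$edges$v2 == v)
      partners <- ifelse(g$edges$v1[inc] == v, g$edges$v2[inc],
                         g$edges$v1[inc])
      edge_dirs <- t(vapply(partners, function(p) unit(pos[p, ] - pos[v, ]),
                            numeric(3)))
      ctr <- colMeans(b$xyz)
      binder_dirs <- t(vapply(b$binder_idx,
                              function(i) unit(b$xyz[i, ] - ctr), numeric(3)))
      al <- align_binders(binder_dirs, edge_dirs)
      xyz <- sweep(b$xyz, 2, ctr) %*% t(al$rot)
      xyz <- sweep(xyz, 2, sc * pos[v, ], "+")
      # binder i of the block serves edge inc[al$perm[i]]
      list(xyz = xyz, rot = al$rot,
           binder_edges = setNames(inc[al$perm], b$binder_idx))
    })
  }

  if (is.null(scale)) {
    scale <- assembly_scale(g, blocks_by_vertex, place_at, sigma_bar)
  }
  placed <- place_at(scale)
  list(placed = placed, blocks = blocks_by_vertex, scale = scale)
}

#' Form inter-building-block bonds and enumerate force-field terms
#'
#' Adds one constructed bond per topology edge between the binder beads
#' assigned to that edge, the b-a-c angle terms at each ditopic binder (at
#' the block's stored target), centre-binder-partner straightness angles at
#' 180 degrees, the optional preorganisation torsion per ditopic block
#' (quadruple b-a-a-b, minimum at 0), and the excluded-volume pair list with
#' pairs within two bonds exempt.
#'
#' @param g a `topology_graph`.
#' @param placement result of [place_building_blocks()].
#' @param torsion `"on"` (preorganised, restricted b-a-a-b torsion) or
#'   `"off"` (flexible).
#' @param params [forcefield_params()].
#' @param straightness_angles add the 180-degree centre-binder-partner
#'   angle terms (default `TRUE`).
#' @return a `cage_model`.
#' @export
form_bonds_and_terms <- function(g, placement, torsion = c("on", "off"),
                                 params = forcefield_params(),
                                 straightness_angles = TRUE) {
  torsion <- match.arg(torsion)
  placed <- placement$placed
  blocks <- placement$blocks
  nb <- vapply(blocks, function(b) nrow(b$beads), integer(1))
  offset <- cumsum(c(0L, nb[-length(nb)]))

  beads <- purrr::map_dfr(seq_along(blocks), function(v) {
    b <- blocks[[v]]
    mutate(b$beads, vertex = g$vertices$id[v], arity = b$arity,
           local = dplyr::row_number(),
           binder = .data$local %in% b$binder_idx)
  })
  beads$index <- seq_len(nrow(beads))
  xyz <- do.call(rbind, lapply(placed, `[[`, "xyz"))

  # intra-block terms
  bonds <- purrr::map_dfr(seq_along(blocks), function(v) {
    b <- blocks[[v]]
    tibble(i = b$bonds$i + offset[v], j = b$bonds$j + offset[v],
           r0 = b$bonds$r0, k = params$k_bond, constructed = FALSE)
  })
  angles <- purrr::map_dfr(seq_along(blocks), function(v) {
    b <- blocks[[v]]
    tibble(i = b$angles$i + offset[v], j = b$angles$j + offset[v],
           k = b$angles$k + offset[v], theta0 = b$angles$theta0,
           kf = params$k_angle)
  })

  # one constructed bond per edge, between the binders assigned to it
  binder_on_edge <- function(v, e) {
    be <- placed[[v]]$binder_edges
    loc <- as.integer(names(be)[be == e])
    if (length(loc) != 1) {
      abort(paste0("edge ", e, " has no free binder on vertex ", v))
    }
    loc + offset[v]
  }
  new_bonds <- purrr::map_dfr(seq_len(nrow(g$edges)), function(e) {
    v1 <- g$edges$v1[e]; v2 <- g$edges$v2[e]
    i <- binder_on_edge(v1, e); j <- binder_on_edge(v2, e)
    tibble(i = i, j = j,
           r0 = mix_r0(beads$bond_r[i], beads$bond_r[j]),
           k = params$k_bond, constructed = TRUE)
  })
  bonds <- bind_rows(bonds, new_bonds)

  # angle terms created by the new bonds
  new_angles <- purrr::map_dfr(seq_len(nrow(new_bonds)), function(r) {
    i <- new_bonds$i[r]; j <- new_bonds$j[r]
    purrr::map_dfr(list(c(i, j), c(j, i)), function(pr) {
      bi <- pr[1]; partner <- pr[2]
      v <- match(beads$vertex[bi], g$vertices$id)
      blk <- blocks[[v]]
      ctr <- blk$centre_idx + offset[v]
      if (blk$arity == 2L) {
        # partner(b) - binder(a) - centre(c) at the ditopic target
        tibble(i = partner, j = bi, k = ctr, theta0 = blk$bac_angle,
               kf = params$k_angle)
      } else if (straightness_angles) {
        # centre - binder - partner straightness
        tibble(i = ctr, j = bi, k = partner, theta0 = 180,
               kf = params$k_angle)
      } else {
        tibble()
      }
    })
  })
  angles <- bind_rows(angles, new_angles)

  # preorganisation torsion: (b, a, a, b) per ditopic block
  empty_torsions <- tibble(i = integer(), j = integer(), k = integer(),
                           l = integer(), phi0 = numeric(), p = numeric(),
                           kf = numeric())
  torsions <- empty_torsions
  if (torsion == "on") {
    di_vertices <- which(vapply(blocks, function(b) b$arity == 2L, logical(1)))
    torsions <- purrr::map_dfr(di_vertices, function(v) {
      blk <- blocks[[v]]
      a1 <- blk$binder_idx[1] + offset[v]
      a2 <- blk$binder_idx[2] + offset[v]
      b1 <- bond_partner(bonds, a1, constructed_only = TRUE)
      b2 <- bond_partner(bonds, a2, constructed_only = TRUE)
      if (is.na(b1) || is.na(b2)) return(tibble())
      tibble(i = b1, j = a1, k = a2, l = b2,
             phi0 = 180, p = params$p, kf = params$k_torsion)
    })
    if (nrow(torsions) == 0) torsions <- empty_torsions
  }

  exempt <- exempt_pairs(nrow(beads), bonds)
  nb_pairs <- nonbonded_pairs(beads, exempt, params)

  structure(
    list(topology = g$name, beads = beads, xyz = xyz, bonds = bonds,
         angles = angles, torsions = torsions, nb_pairs = nb_pairs,
         torsion_state = torsion, n_building_blocks = g$n_building_blocks,
         scale = placement$scale, offsets = offset),
    class = "cage_model"
  )
}

bond_partner <- function(bonds, idx, constructed_only = FALSE) {
  b <- if (constructed_only) bonds[bonds$constructed, ] else bonds
  hit <- c(b$j[b$i == idx], b$i[b$j == idx])
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# pairs within <= 2 bonds of each other (the bondCutoff behaviour)
exempt_pairs <- function(n, bonds) {
  adj <- Matrix::sparseMatrix(i = c(bonds$i, bonds$j),
                              j = c(bonds$j, bonds$i),
                              x = 1, dims = c(n, n))
  reach <- adj + adj %*% adj
  idx <- Matrix::which(reach != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx
}

nonbonded_pairs <- function(beads, exempt, params) {
  n <- nrow(beads)
  all_pairs <- t(combn(n, 2))
  key <- all_pairs[, 1] * (n + 1) + all_pairs[, 2]
  ex_key <- exempt[, 1] * (n + 1) + exempt[, 2]
  keep <- all_pairs[!key %in% ex_key, , drop = FALSE]
  sig <- (beads$sigma[keep[, 1]] + beads$sigma[keep[, 2]]) / 2
  eps <- sqrt(beads$epsilon[keep[, 1]] * beads$epsilon[keep[, 2]])
  tibble(i = keep[, 1], j = keep[, 2], sigma = sig, epsilon = eps,
         cutoff = params$ev_cutoff_mult * sig)
}

#' Build a cage model in one call
#'
#' Convenience wrapper around [place_building_blocks()] and
#' [form_bonds_and_terms()].
#'
#' @inheritParams place_building_blocks
#' @inheritParams form_bonds_and_terms
#' @return a `cage_model`.
#' @examples
#' cage <- build_cage(get_topology("Tri2Di3"),
#'                    list(make_tritopic(120), make_ditopic(120)))
#' @export
build_cage <- function(g, blocks, torsion = c("on", "off"),
                       params = forcefield_params(), scale = NULL,
                       straightness_angles = TRUE) {
  if (is.character(g)) g <- get_topology(g)
  placement <- place_building_blocks(g, blocks, scale = scale)
  form_bonds_and_terms(g, placement, torsion = torsion, params = params,
                       straightness_angles = straightness_angles)
}

#' @exportS3Method base::print
print.cage_model <- function(x, ...) {
  cat(sprintf(
    "<cage_model %s> %d beads, %d building blocks, %d bonds (%d constructed),\n  %d angles, %d torsions (torsion %s), %d excluded-volume pairs\n",
    x$topology, nrow(x$beads), x$n_building_blocks, nrow(x$bonds),
    sum(x$bonds$constructed), nrow(x$angles), nrow(x$torsions),
    x$torsion_state, nrow(x$nb_pairs)))
  invisible(x)
}
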