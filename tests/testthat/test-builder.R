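test_that("term counts follow from the topology graph", {
  cage <- build_cage("Tri4Di6", list(make_tritopic(120), make_ditopic(135)),
                     torsion = "on")
  expect_equal(nrow(cage$beads), 4 * 4 + 6 * 3)
  expect_equal(sum(cage$bonds$constructed), 12)   # one per edge
  # per constructed bond at an a bead: one b-a-c angle; per bond at a b
  # bead: one centre-binder-partner straightness angle
  bac <- cage$angles$theta0 == 135
  expect_equal(sum(bac), 12)
  straight <- cage$angles$theta0 == 180 &
    cage$angles$j %in% cage$beads$index[cage$beads$class == "b"]
  expect_equal(sum(straight), 12)
  expect_equal(nrow(cage$torsions), 6)            # one per ditopic block

  off <- build_cage("Tri4Di6", list(make_tritopic(120), make_ditopic(135)),
                    torsion = "off")
  expect_equal(nrow(off$torsions), 0)
})

test_that("Tet6Tri8 has binder-binder bonds and no ditopic terms", {
  cage <- build_cage("Tet6Tri8", list(make_tetratopic(90), make_tritopic(90)),
                     torsion = "on")
  expect_equal(sum(cage$bonds$constructed), 24)
  expect_equal(nrow(cage$torsions), 0)
  con <- cage$bonds[cage$bonds$constructed, ]
  expect_true(all(cage$beads$class[con$i] == "b"))
  expect_true(all(cage$beads$class[con$j] == "b"))
})

test_that("every binder is used exactly once and the bond graph is connected", {
  for (nm in c("Tri2Di3", "Tri4_2Di6", "Tet4_2Di8", "Tet8Di16")) {
    cage <- build_cage(nm, list(make_ditopic(130), make_tritopic(110),
                                make_tetratopic(85)), torsion = "on")
    con <- cage$bonds[cage$bonds$constructed, ]
    ends <- c(con$i, con$j)
    binders <- cage$beads$index[cage$beads$binder]
    expect_equal(sort(ends), sort(binders), info = nm)
    # all beads in one bonded component
    n <- nrow(cage$beads)
    adj <- Matrix::sparseMatrix(i = c(cage$bonds$i, cage$bonds$j),
                                j = c(cage$bonds$j, cage$bonds$i),
                                x = 1, dims = c(n, n))
    reach <- rep(FALSE, n); reach[1] <- TRUE
    repeat {
      new <- as.logical(adj %*% reach > 0) | reach
      if (identical(new, reach)) break
      reach <- new
    }
    expect_true(all(reach), info = nm)
  }
})

test_that("rebuilding gives identical term lists and coordinates", {
  b <- list(make_tritopic(110), make_ditopic(125))
  c1 <- build_cage("Tri4Di6", b, torsion = "on")
  c2 <- build_cage("Tri4Di6", b, torsion = "on")
  expect_identical(c1$bonds, c2$bonds)
  expect_identical(c1$angles, c2$angles)
  expect_identical(c1$torsions, c2$torsions)
  expect_equal(c1$xyz, c2$xyz)
})

test_that("exclusion exemptions cover exactly the <= 2-bond pairs", {
  cage <- build_cage("Tri2Di3", list(make_tritopic(120), make_ditopic(120)),
                     torsion = "off")
  n <- nrow(cage$beads)
  # graph distances by BFS on the bond graph
  adj <- lapply(seq_len(n), function(i) {
    c(cage$bonds$j[cage$bonds$i == i], cage$bonds$i[cage$bonds$j == i])
  })
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  dm <- t(vapply(seq_len(n), bfs_dist, numeric(n)))
  pair_key <- cage$nb_pairs$i * (n + 1) + cage$nb_pairs$j
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_equal(!((i * (n + 1) + j) %in% pair_key), dm[i, j] <= 2,
                   info = paste(i, j))
    }
  }
})

test_that("no two beads coincide after placement and bonds start unstretched", {
  for (nm in c("Tri4Di6", "Tet6Di12")) {
    cage <- build_cage(nm, list(make_ditopic(120), make_tritopic(110),
                                make_tetratopic(90)))
    d <- as.matrix(stats::dist(cage$xyz))
    diag(d) <- Inf
    expect_gt(min(d), 0.5)
    con <- cage$bonds[cage$bonds$constructed, ]
    blen <- sqrt(rowSums((cage$xyz[con$i, , drop = FALSE] -
                            cage$xyz[con$j, , drop = FALSE])^2))
    expect_true(all(blen >= con$r0 - 1e-9), info = nm)
  }
})

test_that("arity mismatch raises an assembly error naming the vertex", {
  g <- get_topology("Tri4Di6")
  expect_error(
    place_building_blocks(g, list(make_ditopic(120), make_tetratopic(90))),
    "arity|vertex"
  )
})
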