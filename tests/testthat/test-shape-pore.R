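test_that("every registered reference measures zero against itself", {
  for (l in list_reference_shapes()) {
    expect_lt(cshm(reference_shape(l)$xyz, l)$measure, 1e-8)
  }
})

test_that("the shape measure is invariant to motion, scale and relabelling", {
  set.seed(21)
  cube <- reference_shape("CU-8")$xyz
  for (rep in 1:3) {
    moved <- cube[sample(8), ] %*% random_rotation() * runif(1, 0.5, 3)
    moved <- sweep(moved, 2, rnorm(3, sd = 4), "+")
    expect_lt(cshm(moved, "CU-8")$measure, 1e-8)
  }
  # general invariance on a noisy (non-symmetric) point set
  pts <- cube + matrix(rnorm(24, sd = 0.2), 8, 3)
  m0 <- cshm(pts, "CU-8")$measure
  moved <- pts[sample(8), ] %*% random_rotation() * 1.7
  expect_equal(cshm(moved, "CU-8")$measure, m0, tolerance = 1e-8)
})

test_that("tetrahedron against the square is the classic 33.33", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(cshm(tet, "SP-4")$measure, 100 / 3, tolerance = 1e-6)
  expect_equal(oracle_cshm(tet, reference_shape("SP-4")$xyz), 100 / 3,
               tolerance = 1e-6)
})

test_that("pruned permutation search equals exhaustive enumeration", {
  set.seed(22)
  refs <- c("TP-3", "T-4", "SP-4", "OC-6", "TPR-6")
  for (rep in 1:10) {
    for (l in refs) {
      ref <- reference_shape(l)
      pts <- matrix(rnorm(3 * ref$n), ref$n, 3)
      expect_equal(cshm(pts, ref)$measure, oracle_cshm(pts, ref$xyz),
                   tolerance = 1e-9, info = l)
    }
  }
})

test_that("the measure shrinks continuously with vertex noise", {
  set.seed(23)
  oc <- reference_shape("OC-6")$xyz
  sds <- c(0.3, 0.1, 0.02)
  med <- vapply(sds, function(s) {
    stats::median(vapply(1:12, function(i) {
      cshm(oc + matrix(rnorm(18, sd = s), 6, 3), "OC-6")$measure
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  expect_lt(med[3], 0.1)
})

test_that("degenerate and mismatched inputs are rejected", {
  expect_error(cshm(matrix(0, 6, 3), "OC-6"), "degenerate")
  expect_error(cshm(matrix(rnorm(12), 4, 3), "OC-6"), "point count")
  expect_error(reference_shape("XX-9"), "unknown")
})

test_that("building-block centroids come out per vertex in cage order", {
  cage <- build_cage("Tri4Di6", list(make_tritopic(120), make_ditopic(125)))
  expect_equal(nrow(bb_centroids(cage, "tritopic")), 4)
  expect_equal(nrow(bb_centroids(cage, "ditopic")), 6)
  expect_error(bb_centroids(cage, "tetratopic"), "no tetratopic")
  tt <- build_cage("Tet6Tri8", list(make_tetratopic(90), make_tritopic(90)))
  expect_equal(nrow(bb_centroids(tt, "tetratopic")), 6)
  expect_equal(nrow(bb_centroids(tt, "tritopic")), 8)
})

test_that("as-constructed centroid sets sit on their ideal polyhedra", {
  # construction places tritopic blocks of Tri8Di12 on cube vertices
  cage <- build_cage("Tri8Di12", list(make_tritopic(110), make_ditopic(125)))
  expect_lt(cshm(bb_centroids(cage, "tritopic"), "CU-8")$measure, 1e-8)
  oct <- build_cage("Tet6Di12", list(make_tetratopic(90), make_ditopic(135)))
  expect_lt(cshm(bb_centroids(oct, "tetratopic"), "OC-6")$measure, 1e-8)
})

test_that("shape reports follow the topology mapping", {
  cage <- build_cage("Tri6Di9", list(make_tritopic(90), make_ditopic(120)))
  rep1 <- shape_report(cage)
  expect_equal(names(rep1), "TPR-6")
  tt <- build_cage("Tet6Tri8", list(make_tetratopic(90), make_tritopic(90)))
  rep2 <- shape_report(tt)
  expect_setequal(names(rep2), c("OC-6", "CU-8"))
  big <- build_cage("Tet12Di24", list(make_tetratopic(90), make_ditopic(150)))
  expect_length(shape_report(big), 0)
})

test_that("pore radius is the centroid-to-surface distance, floored at zero", {
  # six sigma = 1 beads at octahedron vertices 3 A out: 3 - 0.5 = 2.5
  cage <- list(
    xyz = 3 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1)),
    beads = tibble::tibble(sigma = rep(1, 6))
  )
  class(cage) <- "cage_model"
  expect_equal(pore_radius(cage), 2.5)
  # a bead at the centroid floors the radius at zero
  cage$xyz <- rbind(cage$xyz, c(0, 0, 0))
  cage$beads <- tibble::tibble(sigma = rep(1, 7))
  expect_equal(pore_radius(cage), 0)
  # scaling up the structure opens the pore
  built <- build_cage("Tet6Di12", list(make_tetratopic(90), make_ditopic(135)))
  r1 <- pore_radius(built)
  built$xyz <- built$xyz * 2
  expect_gt(pore_radius(built), r1)
})
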