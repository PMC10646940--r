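test_that("single-term energies match hand calculations", {
  cage <- strained_test_cage()
  # zero out everything, add one stretched bond: 1/2 * 1000 * 0.1^2 = 5
  c1 <- cage
  c1$angles <- c1$angles[0, ]; c1$torsions <- c1$torsions[0, ]
  c1$nb_pairs <- c1$nb_pairs[0, ]
  c1$bonds <- tibble::tibble(i = 1L, j = 2L, r0 = 2, k = 1000,
                             constructed = FALSE)
  c1$xyz <- matrix(0, nrow(cage$beads), 3)
  c1$xyz[2, 1] <- 2.1
  e <- cage_energy(c1)
  expect_equal(e$E_bond, 5)
  expect_equal(e$E_total, 5)

  # one restricted torsion at phi = 180: k (1 + cos(180 - 180)) = 2k = 100
  c2 <- cage
  c2$bonds <- c2$bonds[0, ]; c2$angles <- c2$angles[0, ]
  c2$nb_pairs <- c2$nb_pairs[0, ]
  c2$torsions <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L,
                                phi0 = 180, p = 1, kf = 50)
  c2$xyz <- matrix(0, nrow(cage$beads), 3)
  c2$xyz[1, ] <- c(1, 1, 0)
  c2$xyz[2, ] <- c(1, 0, 0)
  c2$xyz[3, ] <- c(-1, 0, 0)
  c2$xyz[4, ] <- c(-1, -1, 0) # trans arrangement, phi = 180
  expect_equal(cage_energy(c2)$E_torsion, 100)
  c2$xyz[4, ] <- c(-1, 1, 0)  # cis, phi = 0: the restricted minimum
  expect_equal(cage_energy(c2)$E_torsion, 0, tolerance = 1e-12)
})

test_that("a block built at equilibrium has zero internal energy", {
  cage <- build_cage("Tri2Di3", list(make_tritopic(120), make_ditopic(120)),
                     torsion = "off")
  # keep only intra-block terms: drop constructed bonds and their angles
  intra <- cage
  intra$bonds <- cage$bonds[!cage$bonds$constructed, ]
  keep <- vapply(seq_len(nrow(cage$angles)), function(r) {
    v <- unique(cage$beads$vertex[c(cage$angles$i[r], cage$angles$j[r],
                                    cage$angles$k[r])])
    length(v) == 1
  }, logical(1))
  intra$angles <- cage$angles[keep, ]
  intra$nb_pairs <- cage$nb_pairs[0, ]
  expect_equal(cage_energy(intra)$E_total, 0, tolerance = 1e-16)
})

test_that("analytic gradient agrees with finite differences", {
  set.seed(11)
  for (rep in 1:3) {
    cage <- strained_test_cage()
    xyz <- cage$xyz + matrix(rnorm(length(cage$xyz), sd = 0.3),
                             nrow(cage$xyz))
    g <- cage_gradient(cage, xyz)
    fd <- oracle_fd_gradient(cage, xyz)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("energy is invariant to rigid motion", {
  set.seed(12)
  cage <- strained_test_cage()
  e0 <- cage_energy(cage)$E_total
  for (rep in 1:3) {
    r <- random_rotation()
    moved <- cage$xyz %*% r
    moved <- sweep(moved, 2, rnorm(3, sd = 10), "+")
    expect_equal(cage_energy(cage, moved)$E_total, e0, tolerance = 1e-8)
  }
})

test_that("excluded volume is purely repulsive and exemption-monotone", {
  cage <- strained_test_cage()
  e_with <- cage_energy(cage)$E_excl_vol
  expect_gte(e_with, 0)
  # removing the exemptions (treating every pair as interacting) can only
  # increase the excluded-volume energy
  all_pairs <- t(utils::combn(nrow(cage$beads), 2))
  sig <- (cage$beads$sigma[all_pairs[, 1]] + cage$beads$sigma[all_pairs[, 2]]) / 2
  noex <- cage
  noex$nb_pairs <- tibble::tibble(
    i = all_pairs[, 1], j = all_pairs[, 2], sigma = sig,
    epsilon = sqrt(cage$beads$epsilon[all_pairs[, 1]] *
                     cage$beads$epsilon[all_pairs[, 2]]),
    cutoff = 3 * sig
  )
  expect_gte(cage_energy(noex)$E_excl_vol, e_with)
})

test_that("minimisation relaxes strain and never goes uphill", {
  cage <- strained_test_cage()
  e0 <- cage_energy(cage)$E_total
  m <- minimise_cage(cage)
  expect_lte(m$energy$E_total, e0)
  # a single stretched bond relaxes back to r0
  simple <- cage
  simple$angles <- simple$angles[0, ]; simple$torsions <- simple$torsions[0, ]
  simple$nb_pairs <- simple$nb_pairs[0, ]
  simple$bonds <- tibble::tibble(i = 1L, j = 2L, r0 = 2, k = 1000,
                                 constructed = FALSE)
  ms <- minimise_cage(simple)
  r <- sqrt(sum((ms$cage$xyz[1, ] - ms$cage$xyz[2, ])^2))
  expect_equal(r, 2, tolerance = 1e-5)
  # starting at a minimum stays there
  m2 <- minimise_cage(m$cage)
  expect_equal(m2$energy$E_total, m$energy$E_total, tolerance = 1e-6)
})

test_that("constrained minimisation holds the frozen bonds", {
  cage <- strained_test_cage()
  intra <- which(!cage$bonds$constructed)
  len0 <- sqrt(rowSums((cage$xyz[cage$bonds$i[intra], , drop = FALSE] -
                          cage$xyz[cage$bonds$j[intra], , drop = FALSE])^2))
  cm <- constrained_minimise(cage, frozen = "intra")
  len1 <- sqrt(rowSums((cm$cage$xyz[cage$bonds$i[intra], , drop = FALSE] -
                          cm$cage$xyz[cage$bonds$j[intra], , drop = FALSE])^2))
  expect_lt(max(abs(len1 - len0)), 1e-4)
  # constructed bonds move closer to their targets
  con <- which(cage$bonds$constructed)
  dev0 <- abs(sqrt(rowSums((cage$xyz[cage$bonds$i[con], , drop = FALSE] -
                              cage$xyz[cage$bonds$j[con], , drop = FALSE])^2)) -
                cage$bonds$r0[con])
  dev1 <- abs(sqrt(rowSums((cm$cage$xyz[cage$bonds$i[con], , drop = FALSE] -
                              cm$cage$xyz[cage$bonds$j[con], , drop = FALSE])^2)) -
                cage$bonds$r0[con])
  expect_lt(mean(dev1), mean(dev0) + 1e-9)
  # freezing nothing reduces to plain minimisation
  free <- constrained_minimise(cage, frozen = "none")
  plain <- minimise_cage(cage)
  expect_equal(free$energy$E_total, plain$energy$E_total, tolerance = 1e-4)
})

test_that("softened dynamics is seeded, stochastic, and quenches at kBT = 0", {
  cage <- strained_test_cage()
  f1 <- soft_dynamics(cage, kBT = 2.5, n_steps = 300, n_frames = 3, seed = 4)
  f2 <- soft_dynamics(cage, kBT = 2.5, n_steps = 300, n_frames = 3, seed = 4)
  expect_identical(f1, f2)
  expect_gt(max(abs(f1[[2]] - f1[[1]])), 0)
  f0 <- soft_dynamics(cage, kBT = 0, n_steps = 300, n_frames = 3, seed = 4)
  e_start <- cage_energy(cage)$E_total
  e_end <- cage_energy(cage, f0[[3]])$E_total
  expect_lte(e_end, e_start)
})
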