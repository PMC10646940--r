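# A synthetic scan table with known stability structure, used to exercise
# the classification layer without running optimisations.
fake_scan <- function() {
  tb <- tidyr::expand_grid(
    topology = c("Tri4Di6", "Tri8Di12"),
    torsion_state = "on",
    ditopic_angle = c(100, 120, 140),
    tritopic_angle = c(100, 120)
  )
  tb$family <- "3C"
  tb$tetratopic_angle <- NA_real_
  tb$n_building_blocks <- ifelse(tb$topology == "Tri4Di6", 10L, 20L)
  # Tri4Di6 stable at ditopic <= 120; Tri8Di12 stable only at (140, 120)
  tb$E_b <- ifelse(tb$topology == "Tri4Di6" & tb$ditopic_angle <= 120, 0.1,
                   ifelse(tb$topology == "Tri8Di12" &
                            tb$ditopic_angle == 140 &
                            tb$tritopic_angle == 120, 0.2, 5))
  tb$stable <- tb$E_b <= 0.3
  tb$converged <- TRUE
  tb$seed <- 1L
  tb$E_b_spread <- 0
  class(tb) <- c("cage_scan", class(tb))
  attr(tb, "threshold") <- 0.3
  tb
}

test_that("classification follows the stable-set size", {
  oc <- classify_outcomes(fake_scan(), threshold = 0.3)
  expect_equal(nrow(oc), 6) # 3 ditopic x 2 tritopic combos
  get <- function(di, tri) oc[oc$ditopic_angle == di & oc$tritopic_angle == tri, ]
  expect_equal(get(100, 100)$outcome, "selective")
  expect_equal(get(140, 100)$outcome, "unstable")
  expect_equal(get(140, 120)$outcome, "selective")
  expect_equal(get(120, 120)$outcome, "selective")
  # push both topologies stable: mixed, smallest wins by block count
  oc2 <- classify_outcomes(fake_scan(), threshold = 10)
  expect_true(all(oc2$outcome == "mixed"))
  expect_true(all(oc2$smallest_stable == "Tri4Di6"))
})

test_that("stable sets are monotone in the threshold", {
  sc <- fake_scan()
  oc_lo <- classify_outcomes(sc, threshold = 0.15)
  oc_hi <- classify_outcomes(sc, threshold = 0.3)
  for (r in seq_len(nrow(oc_lo))) {
    expect_true(all(oc_lo$stable_set[[r]] %in% oc_hi$stable_set[[r]]))
  }
})

test_that("percent-selected hits its limits and interior maximum", {
  sc <- fake_scan()
  curve <- percent_selected(sc, thresholds = c(0, 0.25, 100), family = "3C",
                            torsion = "on")
  expect_equal(curve$percent_selected[1], 0)   # nothing stable at 0
  expect_equal(curve$percent_selected[3], 0)   # everything mixed at infinity
  expect_gt(curve$percent_selected[2], 0)      # interior maximum
  # constructed fixture where exactly one topology is stable per combo
  sc2 <- sc[sc$topology == "Tri4Di6", ]
  sc2$E_b <- 0.1
  expect_equal(percent_selected(sc2, thresholds = 0.3, family = "3C",
                                torsion = "on")$percent_selected, 100)
})

test_that("accessible map covers the full rectangular grid", {
  oc <- classify_outcomes(fake_scan(), threshold = 0.3)
  mp <- accessible_map(oc)
  expect_equal(nrow(mp), 6)
  expect_setequal(unique(mp$outcome), c("selective", "unstable"))
  # dropping a grid point yields an unknown row, not a missing row
  mp2 <- accessible_map(oc[-1, ])
  expect_equal(nrow(mp2), 6)
  expect_true("unknown" %in% mp2$outcome)
})

test_that("proportion accessible counts stable grid points", {
  sc <- fake_scan()
  expect_equal(proportion_accessible(sc, "Tri4Di6", threshold = 0.3,
                                     torsion = "on"), 4 / 6)
  expect_equal(proportion_accessible(sc, "Tri8Di12", threshold = 0.3,
                                     torsion = "on"), 1 / 6)
  sc$E_b <- 0.01
  expect_equal(proportion_accessible(sc, "Tri4Di6", threshold = 0.3,
                                     torsion = "on"), 1)
})

test_that("a real mini-scan is deterministic and order-invariant", {
  grid <- angle_grid(ditopic = c(115, 135), tritopic = 120,
                     tetratopic = numeric(0), torsion = "on")
  r1 <- scan_phase_space(c("Tri2Di3", "Tri4Di6"), grid = grid, seed = 5)
  r2 <- scan_phase_space(c("Tri4Di6", "Tri2Di3"), grid = grid, seed = 5)
  expect_equal(nrow(r1), 4)
  m1 <- dplyr::arrange(r1, topology, ditopic_angle)
  m2 <- dplyr::arrange(r2, topology, ditopic_angle)
  expect_equal(m1$E_b, m2$E_b)
  expect_true(all(m1$stable == (m1$E_b <= 0.3)))
  # empty grid gives an empty result
  empty <- scan_phase_space("Tri4Di6",
                            grid = angle_grid(ditopic = numeric(0),
                                              tritopic = numeric(0),
                                              tetratopic = numeric(0),
                                              torsion = "on"))
  expect_equal(nrow(empty), 0)
})
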