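#' Angle grid for phase-space scans
#'
#' The cage space is discretised over the target internal angle values:
#' ditopic b-a-c angles, tritopic b-n-b angles and tetratopic adjacent
#' b-m-b angles, crossed with one or both torsion states.
#'
#' @param ditopic ditopic target angles (degrees), default 90-180 step 5.
#' @param tritopic tritopic target angles (degrees), default 50-120 step 10.
#' @param tetratopic tetratopic target angles (degrees), default 50-90
#'   step 10.
#' @param torsion subset of `c("on", "off")`.
#' @return an `angle_grid` list.
#' @export
angle_grid <- function(ditopic = seq(90, 180, by = 5),
                       tritopic = seq(50, 120, by = 10),
                       tetratopic = seq(50, 90, by = 10),
                       torsion = c("on", "off")) {
  stopifnot(length(torsion) >= 1, all(torsion %in% c("on", "off")))
  if (length(ditopic) && any(ditopic < 90 | ditopic > 180)) {
    abort("ditopic angles must lie in [90, 180]")
  }
  if (length(tritopic) && any(tritopic <= 0 | tritopic > 120)) {
    abort("tritopic angles must lie in (0, 120]")
  }
  if (length(tetratopic) && any(tetratopic <= 0 | tetratopic > 90)) {
    abort("tetratopic angles must lie in (0, 90]")
  }
  structure(list(ditopic = ditopic, tritopic = tritopic,
                 tetratopic = tetratopic, torsion = torsion),
            class = "angle_grid")
}

topology_family <- function(g) {
  ar <- sort(unique(g$vertices$arity))
  if (identical(ar, c(3L, 4L))) "34C"
  else if (3L %in% ar) "3C"
  else "4C"
}

# angle combos a topology needs, as a tibble of
# (ditopic_angle, tritopic_angle, tetratopic_angle)
grid_combos <- function(g, grid) {
  ar <- unique(g$vertices$arity)
  has2 <- 2L %in% ar; has3 <- 3L %in% ar; has4 <- 4L %in% ar
  di <- if (has2) grid$ditopic else NA_real_
  tri <- if (has3) grid$tritopic else NA_real_
  tet <- if (has4) grid$tetratopic else NA_real_
  tidyr::expand_grid(ditopic_angle = di, tritopic_angle = tri,
                     tetratopic_angle = tet)
}

blocks_for_combo <- function(g, combo, bead_set) {
  ar <- unique(g$vertices$arity)
  blocks <- list()
  if (2L %in% ar) {
    blocks <- c(blocks, list(make_ditopic(
      combo$ditopic_angle, bead_a = bead_set$a, bead_c = bead_set$c)))
  }
  if (3L %in% ar) {
    blocks <- c(blocks, list(make_tritopic(
      combo$tritopic_angle, bead_n = bead_set$n, bead_b = bead_set$b)))
  }
  if (4L %in% ar) {
    blocks <- c(blocks, list(make_tetratopic(
      combo$tetratopic_angle, bead_m = bead_set$m, bead_b = bead_set$b)))
  }
  blocks
}

#' Default bead set
#'
#' One [bead_spec()] per bead class with the default bond radius (2 A),
#' size (1 A) and strength (10 kJ/mol).
#'
#' @param bond_r bond radius applied to every class (A).
#' @return named list of bead specs keyed by class.
#' @export
default_bead_set <- function(bond_r = 2) {
  setNames(lapply(c("a", "b", "c", "m", "n"), bead_spec, bond_r = bond_r),
           c("a", "b", "c", "m", "n"))
}

#' Scan an angle grid across topologies
#'
#' Builds and fully optimises one cage per (topology, angle combo, torsion
#' state) and records the optimised energy per building block. Combos are
#' restricted to the building-block types each topology needs. The per-point
#' seeds are derived deterministically from `seed`, so results do not depend
#' on evaluation order.
#'
#' @param topologies character vector of topology names (or a list of
#'   `topology_graph`s).
#' @param grid an [angle_grid()].
#' @param params [forcefield_params()].
#' @param threshold accessibility threshold on E_b (kJ/mol); default 0.3.
#' @param seed integer master seed.
#' @param config [search_config()] for the conformer search.
#' @param bead_set bead specs per class, see [default_bead_set()].
#' @param repeats independent optimisation repeats per point (the spread is
#'   recorded in `E_b_spread`); default 1.
#' @return a tibble (class `cage_scan`) with one row per phase point:
#'   topology, family, torsion_state, the three angle columns (NA where
#'   unused), `E_b`, `stable`, `E_b_spread`, `converged`, `seed`.
#' @export
scan_phase_space <- function(topologies, grid = angle_grid(),
                             params = forcefield_params(), threshold = 0.3,
                             seed = 1, config = search_config(),
                             bead_set = default_bead_set(), repeats = 1) {
  if (is.character(topologies)) topologies <- lapply(topologies, get_topology)
  if (inherits(topologies, "topology_graph")) topologies <- list(topologies)
  rows <- list()
  for (g in topologies) {
    combos <- grid_combos(g, grid)
    fam <- topology_family(g)
    for (ci in seq_len(nrow(combos))) {
      combo <- combos[ci, ]
      blocks <- tryCatch(blocks_for_combo(g, combo, bead_set),
                         error = function(e) NULL)
      for (ts in grid$torsion) {
        if (is.null(blocks)) {
          warn(paste0("skipping infeasible combo for ", g$name))
          next
        }
        # seed keyed to the point identity, so results are invariant to
        # topology evaluation order
        key <- paste(g$name, ts, combo$ditopic_angle, combo$tritopic_angle,
                     combo$tetratopic_angle)
        pseed <- sub_seed(seed, key_hash(key))
        ebs <- numeric(repeats)
        conv <- logical(repeats)
        for (r in seq_len(repeats)) {
          cage <- build_cage(g, blocks, torsion = ts, params = params)
          opt <- optimise_cage(cage, config = config,
                               seed = sub_seed(pseed, r))
          ebs[r] <- opt$E_b
          conv[r] <- opt$converged
        }
        rows[[length(rows) + 1]] <- tibble(
          topology = g$name, family = fam, torsion_state = ts,
          ditopic_angle = combo$ditopic_angle,
          tritopic_angle = combo$tritopic_angle,
          tetratopic_angle = combo$tetratopic_angle,
          n_building_blocks = g$n_building_blocks,
          E_b = min(ebs), E_b_spread = diff(range(ebs)),
          stable = min(ebs) <= threshold,
          converged = any(conv), seed = pseed
        )
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("cage_scan", class(out))
  attr(out, "threshold") <- threshold
  out
}

combo_cols <- c("torsion_state", "family", "ditopic_angle",
                "tritopic_angle", "tetratopic_angle")

#' Classify self-sorting outcomes
#'
#' Per building-block combination and torsion state, the outcome is
#' `unstable` (no topology stable), `selective` (exactly one) or `mixed`
#' (two or more). Only topologies sharing the combination's block types
#' (the same family) compete.
#'
#' @param results a `cage_scan` tibble from [scan_phase_space()].
#' @param threshold accessibility threshold on E_b (kJ/mol).
#' @return a tibble with one row per (combo, torsion state): the outcome,
#'   the stable topology set (list column and comma-joined string) and the
#'   smallest stable topology by building-block count.
#' @export
classify_outcomes <- function(results,
                              threshold = attr(results, "threshold") %||% 0.3) {
  results |>
    mutate(stable = .data$E_b <= threshold) |>
    group_by(across(dplyr::all_of(combo_cols))) |>
    summarise(
      n_topologies = dplyr::n_distinct(.data$topology),
      stable_set = list(sort(unique(.data$topology[.data$stable]))),
      .groups = "drop"
    ) |>
    mutate(
      n_stable = vapply(.data$stable_set, length, integer(1)),
      outcome = dplyr::case_when(
        .data$n_stable == 0 ~ "unstable",
        .data$n_stable == 1 ~ "selective",
        TRUE ~ "mixed"
      ),
      stable_topologies = vapply(.data$stable_set, paste,
                                 character(1), collapse = ","),
      smallest_stable = vapply(.data$stable_set, function(s) {
        if (length(s) == 0) return(NA_character_)
        sizes <- vapply(s, function(nm) get_topology(nm)$n_building_blocks,
                        numeric(1))
        s[order(sizes, s)][1]
      }, character(1))
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of selected (self-sorted) combinations versus threshold
#'
#' For each candidate threshold, the percentage of building-block
#' combinations for which exactly one topology is stable.
#'
#' @param results a `cage_scan` covering the family's topologies.
#' @param thresholds numeric vector of E_b thresholds (kJ/mol).
#' @param family `"3C"` or `"4C"`.
#' @param torsion `"on"` or `"off"`.
#' @return tibble with `threshold` and `percent_selected`.
#' @export
percent_selected <- function(results, thresholds = seq(0, 1, by = 0.05),
                             family = c("3C", "4C"),
                             torsion = c("on", "off")) {
  family <- match.arg(family)
  torsion <- match.arg(torsion)
  sub <- filter(results, .data$family == !!family,
                .data$torsion_state == !!torsion)
  purrr::map_dfr(thresholds, function(th) {
    oc <- classify_outcomes(sub, threshold = th)
    tibble(threshold = th,
           percent_selected = 100 * mean(oc$outcome == "selective"))
  })
}

#' Accessible topology map
#'
#' Arranges classified outcomes on the rectangular (polytopic angle,
#' ditopic angle) grid: one row per grid point with the stable-topology
#' set, the outcome label and the smallest stable topology. Grid points
#' without results are filled with outcome `"unknown"`.
#'
#' @param outcomes output of [classify_outcomes()] (a single family and
#'   torsion state).
#' @return a tibble ready for CSV export or [plot_accessible_map()].
#' @export
accessible_map <- function(outcomes) {
  if (dplyr::n_distinct(outcomes$family) > 1 ||
      dplyr::n_distinct(outcomes$torsion_state) > 1) {
    abort("accessible_map expects one family and one torsion state; filter first")
  }
  fam <- outcomes$family[1]
  poly_col <- switch(fam, "3C" = "tritopic_angle", "4C" = "tetratopic_angle",
                     "34C" = "tritopic_angle")
  out <- outcomes |>
    mutate(polytopic_angle = .data[[poly_col]]) |>
    select("torsion_state", "family", "polytopic_angle", "ditopic_angle",
           "outcome", "stable_topologies", "smallest_stable")
  full <- tidyr::expand_grid(
    polytopic_angle = sort(unique(out$polytopic_angle)),
    ditopic_angle = sort(unique(out$ditopic_angle))
  )
  full |>
    left_join(out, by = c("polytopic_angle", "ditopic_angle")) |>
    mutate(outcome = tidyr::replace_na(.data$outcome, "unknown"),
           torsion_state = .data$torsion_state[!is.na(.data$torsion_state)][1],
           family = fam) |>
    arrange(.data$polytopic_angle, .data$ditopic_angle)
}

#' Proportion of the angle grid accessible for one topology
#'
#' @param results a `cage_scan` covering the topology's grid.
#' @param topology topology name.
#' @param threshold accessibility threshold on E_b (kJ/mol).
#' @param torsion `"on"` or `"off"`.
#' @return fraction of grid points with `E_b <= threshold`.
#' @export
proportion_accessible <- function(results, topology,
                                  threshold = attr(results, "threshold") %||% 0.3,
                                  torsion = c("on", "off")) {
  torsion <- match.arg(torsion)
  sub <- filter(results, .data$topology == !!topology,
                .data$torsion_state == !!torsion)
  if (nrow(sub) == 0) abort(paste0("no scan results for ", topology))
  mean(sub$E_b <= threshold)
}
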