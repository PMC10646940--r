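#' Conformer-search configuration
#'
#' Parameters of the multi-step optimisation sequence. The defaults are the
#' study conditions used throughout the package: softened-dynamics stage at
#' `kBT = 2.5` kJ/mol for 2000 steps keeping 8 frames, outward centroid
#' shifts of 1.25x, 1.5x and 2x as anti-collapse restarts, gradient
#' tolerance 1e-2 kJ/mol/A for the search stages and 1e-3 for the final
#' polish (the practical double-precision floor at this force-field scale).
#'
#' @param kBT softened-dynamics thermal energy (kJ/mol).
#' @param md_steps,md_frames dynamics steps and frames kept.
#' @param soften_bond,soften_angle softening multipliers for the dynamics.
#' @param shift_factors outward centroid-shift restart factors.
#' @param tol,final_tol gradient tolerances (kJ/mol/A).
#' @param max_iter per-minimisation iteration cap.
#' @return a `search_config` list.
#' @export
search_config <- function(kBT = 2.5, md_steps = 2000, md_frames = 8,
                          soften_bond = 0.1, soften_angle = 0.1,
                          shift_factors = c(1.25, 1.5, 2),
                          tol = 1e-2, final_tol = 1e-3, max_iter = 3000) {
  structure(list(kBT = kBT, md_steps = md_steps, md_frames = md_frames,
                 soften_bond = soften_bond, soften_angle = soften_angle,
                 shift_factors = shift_factors, tol = tol,
                 final_tol = final_tol, max_iter = max_iter),
            class = "search_config")
}

#' Energy per building block
#'
#' The stability score of a cage: total energy divided by the number of
#' building blocks.
#'
#' @param energy an `energy_breakdown` (or a single total energy).
#' @param n_bbs number of building blocks (>= 1).
#' @return E_b in kJ/mol.
#' @export
energy_per_bb <- function(energy, n_bbs) {
  if (n_bbs < 1) abort("n_bbs must be >= 1")
  e <- if (inherits(energy, "energy_breakdown")) energy$E_total else energy
  e / n_bbs
}

#' Multi-step conformer search for one cage
#'
#' Runs the full optimisation sequence: (1) constrained minimisation with
#' the intra-block bonds held, (2) full minimisation, (3) softened-potential
#' stochastic dynamics, (4) full minimisation of every frame, (5) outward
#' shift of all beads from the cage centroid by each configured factor,
#' (6) full minimisation of each shifted start, (7) tight final
#' minimisation of the best candidate. The candidate with the lowest total
#' energy wins; the whole sequence is reproducible from `seed`.
#'
#' @param cage a `cage_model`.
#' @param config a [search_config()].
#' @param seed integer seed for the dynamics stage.
#' @return a `cage_opt` object: the input cage with optimised coordinates
#'   plus `energy`, `E_b`, `converged`, `trace` (per-step energies) and
#'   `seed`.
#' @export
optimise_cage <- function(cage, config = search_config(), seed = 1) {
  trace <- list()
  note <- function(step, e) {
    trace[[length(trace) + 1]] <<- tibble(step = step, E_total = e$E_total)
  }

  s1 <- constrained_minimise(cage, frozen = "intra", tol = config$tol,
                             max_iter = config$max_iter)
  note("constrained_min", s1$energy)
  s2 <- minimise_cage(s1$cage, tol = config$tol, max_iter = config$max_iter)
  note("full_min", s2$energy)

  candidates <- list(s2)

  frames <- soft_dynamics(s2$cage, kBT = config$kBT,
                          n_steps = config$md_steps,
                          n_frames = config$md_frames, seed = seed,
                          soften_bond = config$soften_bond,
                          soften_angle = config$soften_angle)
  for (f in frames) {
    cf <- s2$cage; cf$xyz <- f
    sf <- minimise_cage(cf, tol = config$tol, max_iter = config$max_iter)
    note("md_frame_min", sf$energy)
    candidates[[length(candidates) + 1]] <- sf
  }

  best_so_far <- candidates[[which.min(vapply(candidates,
                                              function(c) c$energy$E_total,
                                              numeric(1)))]]
  for (fac in config$shift_factors) {
    cs <- best_so_far$cage
    ctr <- colMeans(cs$xyz)
    cs$xyz <- sweep(sweep(cs$xyz, 2, ctr) * fac, 2, ctr, "+")
    ss <- minimise_cage(cs, tol = config$tol, max_iter = config$max_iter)
    note(paste0("shift_min_", fac), ss$energy)
    candidates[[length(candidates) + 1]] <- ss
  }

  best <- candidates[[which.min(vapply(candidates,
                                       function(c) c$energy$E_total,
                                       numeric(1)))]]
  final <- minimise_cage(best$cage, tol = config$final_tol,
                         max_iter = config$max_iter)
  note("final_min", final$energy)
  if (final$energy$E_total > best$energy$E_total) final <- best

  out <- final$cage
  structure(
    list(cage = out, energy = final$energy,
         E_b = energy_per_bb(final$energy, out$n_building_blocks),
         converged = final$converged,
         trace = bind_rows(trace), seed = seed),
    class = "cage_opt"
  )
}

#' @exportS3Method base::print
print.cage_opt <- function(x, ...) {
  cat(sprintf("<cage_opt %s> E_total = %.6g kJ/mol, E_b = %.6g kJ/mol%s\n",
              x$cage$topology, x$energy$E_total, x$E_b,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname optimise_cage
#' @param x a `cage_opt`.
#' @param ... unused.
#' @export
tidy.cage_opt <- function(x, ...) {
  tibble(
    term = c("bond", "angle", "torsion", "excluded_volume", "total"),
    energy = c(x$energy$E_bond, x$energy$E_angle, x$energy$E_torsion,
               x$energy$E_excl_vol, x$energy$E_total)
  )
}

#' @rdname optimise_cage
#' @export
glance.cage_opt <- function(x, ...) {
  tibble(
    topology = x$cage$topology,
    torsion_state = x$cage$torsion_state,
    n_beads = nrow(x$cage$beads),
    n_building_blocks = x$cage$n_building_blocks,
    E_total = x$energy$E_total,
    E_b = x$E_b,
    converged = x$converged,
    seed = x$seed
  )
}

# mean deviations of realised bond lengths / angles from their targets,
# used for parameter-recovery checks
structural_deviation <- function(cage) {
  xyz <- cage$xyz
  blen <- sqrt(rowSums((xyz[cage$bonds$i, , drop = FALSE] -
                          xyz[cage$bonds$j, , drop = FALSE])^2))
  ang <- vapply(seq_len(nrow(cage$angles)), function(t) {
    vec_angle(xyz, cage$angles$i[t], cage$angles$j[t], cage$angles$k[t])
  }, numeric(1))
  list(
    mean_rel_bond_dev = mean(abs(blen - cage$bonds$r0) / cage$bonds$r0),
    mean_angle_dev = mean(abs(ang - cage$angles$theta0))
  )
}
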