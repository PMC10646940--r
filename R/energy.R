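#' Force-field parameters
#'
#' Defaults follow common molecular-mechanics scales: `k_bond` 1e5
#' kJ/mol/nm^2 (stored here as 1e3 kJ/mol/A^2; the nm^-2 to A^-2 conversion
#' is exactly /100), `k_angle` 1e2 kJ/mol/rad^2, `k_torsion` 50 kJ/mol with
#' periodicity `p = 1`. The excluded-volume term is purely repulsive,
#' `sqrt(eps_i eps_j) (sigma_ij / r)^12` with `sigma_ij = (sigma_i +
#' sigma_j) / 2`, truncated and shifted to zero at `ev_cutoff_mult *
#' sigma_ij`. Softening factors scale `k_bond`/`k_angle` during the
#' softened-potential dynamics stage.
#'
#' @param k_bond bond force constant, kJ/mol/A^2.
#' @param k_angle angle force constant, kJ/mol/rad^2.
#' @param k_torsion torsion barrier, kJ/mol.
#' @param p torsion periodicity (integer).
#' @param ev_cutoff_mult excluded-volume cutoff in units of `sigma_ij`.
#' @param soften_bond,soften_angle multipliers used by [soft_dynamics()].
#' @return a `forcefield_params` list.
#' @export
forcefield_params <- function(k_bond = 1e3, k_angle = 1e2, k_torsion = 50,
                              p = 1, ev_cutoff_mult = 3,
                              soften_bond = 0.1, soften_angle = 0.1) {
  stopifnot(k_bond >= 0, k_angle >= 0, k_torsion >= 0, ev_cutoff_mult > 0)
  structure(list(k_bond = k_bond, k_angle = k_angle, k_torsion = k_torsion,
                 p = p, ev_cutoff_mult = ev_cutoff_mult,
                 soften_bond = soften_bond, soften_angle = soften_angle),
            class = "forcefield_params")
}

# pack term tables into the argument list the compiled kernel expects
ff_terms <- function(cage, bond_scale = 1, angle_scale = 1,
                     extra_bonds = NULL) {
  bonds <- cage$bonds
  if (!is.null(extra_bonds)) bonds <- bind_rows(bonds, extra_bonds)
  list(
    bonds = cbind(bonds$i, bonds$j),
    bond_r0 = bonds$r0,
    bond_k = bonds$k * bond_scale,
    angles = cbind(cage$angles$i, cage$angles$j, cage$angles$k),
    ang_th0 = deg2rad(cage$angles$theta0),
    ang_k = cage$angles$kf * angle_scale,
    tors = if (nrow(cage$torsions)) {
      cbind(cage$torsions$i, cage$torsions$j, cage$torsions$k,
            cage$torsions$l)
    } else matrix(integer(), 0, 4),
    tor_phi0 = deg2rad(cage$torsions$phi0),
    tor_p = cage$torsions$p,
    tor_k = cage$torsions$kf,
    pairs = cbind(cage$nb_pairs$i, cage$nb_pairs$j),
    pr_sig = cage$nb_pairs$sigma,
    pr_eps = cage$nb_pairs$epsilon,
    pr_cut = cage$nb_pairs$cutoff
  )
}

terms_energy <- function(xyz, tm) {
  cg_energy_components(xyz, tm$bonds, tm$bond_r0, tm$bond_k,
                       tm$angles, tm$ang_th0, tm$ang_k,
                       tm$tors, tm$tor_phi0, tm$tor_p, tm$tor_k,
                       tm$pairs, tm$pr_sig, tm$pr_eps, tm$pr_cut)
}

terms_gradient <- function(xyz, tm) {
  cg_gradient(xyz, tm$bonds, tm$bond_r0, tm$bond_k,
              tm$angles, tm$ang_th0, tm$ang_k,
              tm$tors, tm$tor_phi0, tm$tor_p, tm$tor_k,
              tm$pairs, tm$pr_sig, tm$pr_eps, tm$pr_cut)
}

as_breakdown <- function(comp) {
  structure(
    list(E_bond = comp[["bond"]], E_angle = comp[["angle"]],
         E_torsion = comp[["torsion"]],
         E_excl_vol = comp[["excluded_volume"]],
         E_total = sum(comp)),
    class = "energy_breakdown"
  )
}

#' @exportS3Method base::print
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "E_total %.6g kJ/mol (bond %.4g, angle %.4g, torsion %.4g, excl.vol %.4g)\n",
    x$E_total, x$E_bond, x$E_angle, x$E_torsion, x$E_excl_vol))
  invisible(x)
}

#' Evaluate the cage force-field energy
#'
#' Total energy is the sum of harmonic bond and angle terms, cosine torsion
#' terms and the repulsive excluded-volume term:
#' `E = E_bond + E_angle + E_torsion + E_excl_vol`.
#'
#' @param cage a `cage_model`.
#' @param xyz optional coordinate matrix overriding `cage$xyz`.
#' @return an `energy_breakdown` with components in kJ/mol.
#' @export
cage_energy <- function(cage, xyz = NULL) {
  check_has_terms(cage)
  if (is.null(xyz)) xyz <- cage$xyz
  stopifnot(all(is.finite(xyz)))
  as_breakdown(terms_energy(xyz, ff_terms(cage)))
}

#' Analytic gradient of the cage energy
#'
#' @inheritParams cage_energy
#' @return an n-by-3 matrix of dE/dx in kJ/mol/A.
#' @export
cage_gradient <- function(cage, xyz = NULL) {
  check_has_terms(cage)
  if (is.null(xyz)) xyz <- cage$xyz
  terms_gradient(xyz, ff_terms(cage))
}

check_has_terms <- function(cage) {
  if (is.null(cage$bonds)) {
    abort(paste0("this cage_model has coordinates only (read without its ",
                 "JSON sidecar); energy operations need the term lists"))
  }
}

run_minimise <- function(xyz, tm, tol, max_iter) {
  n <- nrow(xyz)
  fn <- function(par) sum(terms_energy(matrix(par, n, 3), tm))
  gr <- function(par) as.vector(terms_gradient(matrix(par, n, 3), tm))
  res <- optim(as.vector(xyz), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = tol / 10, factr = 10))
  out <- matrix(res$par, n, 3)
  gnorm <- max(abs(terms_gradient(out, tm)))
  list(xyz = out, converged = gnorm <= tol, gnorm = gnorm)
}

#' Local energy minimisation
#'
#' Gradient-based (L-BFGS) local minimisation of the full force field.
#'
#' @param cage a `cage_model`.
#' @param tol convergence tolerance on the gradient (kJ/mol/A).
#' @param max_iter iteration cap; the best point found is returned either way.
#' @return list with `cage` (updated coordinates), `energy`
#'   (`energy_breakdown`) and `converged`.
#' @export
minimise_cage <- function(cage, tol = 1e-3, max_iter = 3000) {
  tm <- ff_terms(cage)
  e0 <- sum(terms_energy(cage$xyz, tm))
  res <- run_minimise(cage$xyz, tm, tol, max_iter)
  e1 <- sum(terms_energy(res$xyz, tm))
  if (e1 > e0) res$xyz <- cage$xyz # never accept an uphill "minimisation"
  cage$xyz <- res$xyz
  list(cage = cage, energy = cage_energy(cage), converged = res$converged)
}

#' Constrained minimisation with bonds held at their current lengths
#'
#' The listed bonds are restrained stiffly at their instantaneous lengths
#' while every other degree of freedom relaxes. With `frozen = "intra"`
#' (default) all bonds not formed during cage construction are held, which
#' relaxes the newly constructed bonds first.
#'
#' @param cage a `cage_model`.
#' @param frozen `"intra"`, `"none"`, or an integer vector of row indices
#'   into `cage$bonds`.
#' @param restraint_k force constant of the holding restraint (kJ/mol/A^2).
#' @inheritParams minimise_cage
#' @return as [minimise_cage()].
#' @export
constrained_minimise <- function(cage, frozen = "intra", tol = 1e-3,
                                 max_iter = 3000, restraint_k = 1e6) {
  rows <- if (identical(frozen, "intra")) {
    which(!cage$bonds$constructed)
  } else if (identical(frozen, "none")) {
    integer()
  } else {
    stopifnot(all(frozen %in% seq_len(nrow(cage$bonds))))
    as.integer(frozen)
  }
  extra <- NULL
  if (length(rows) > 0) {
    cur_len <- sqrt(rowSums(
      (cage$xyz[cage$bonds$i[rows], , drop = FALSE] -
         cage$xyz[cage$bonds$j[rows], , drop = FALSE])^2))
    extra <- tibble(i = cage$bonds$i[rows], j = cage$bonds$j[rows],
                    r0 = cur_len, k = restraint_k, constructed = FALSE)
  }
  tm <- ff_terms(cage, extra_bonds = extra)
  res <- run_minimise(cage$xyz, tm, tol, max_iter)
  cage$xyz <- res$xyz
  list(cage = cage, energy = cage_energy(cage), converged = res$converged)
}

#' Softened-potential stochastic dynamics
#'
#' Overdamped (Brownian) dynamics under the force field with the bond and
#' angle force constants multiplied by their softening factors, used as a
#' conformer-search stage. Fully reproducible from `seed`.
#'
#' @param cage a `cage_model`.
#' @param kBT thermal energy in kJ/mol (0 gives a downhill quench).
#' @param n_steps number of integration steps.
#' @param n_frames number of evenly spaced frames to return
#'   (`n_frames <= n_steps`).
#' @param seed integer seed.
#' @param dt time step (reduced units; the friction coefficient is 1).
#' @param soften_bond,soften_angle multipliers on the bond/angle force
#'   constants during the run (defaults 0.1).
#' @param guard abort threshold on any |coordinate| (A); frames collected
#'   so far are returned if exceeded.
#' @return list of coordinate matrices (the frames).
#' @export
soft_dynamics <- function(cage, kBT = 2.5, n_steps = 2000, n_frames = 10,
                          seed = 1, dt = 0.005, soften_bond = 0.1,
                          soften_angle = 0.1, guard = 1e4) {
  stopifnot(n_frames <= n_steps)
  tm <- ff_terms(cage, bond_scale = soften_bond, angle_scale = soften_angle)
  xyz <- cage$xyz
  n <- nrow(xyz)
  frame_at <- unique(round(seq_len(n_frames) * n_steps / n_frames))
  frames <- list()
  noise_sd <- sqrt(2 * kBT * dt)
  set.seed(seed)
  for (s in seq_len(n_steps)) {
    g <- terms_gradient(xyz, tm)
    xyz <- xyz - dt * g
    if (kBT > 0) xyz <- xyz + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
    if (max(abs(xyz)) > guard) break
    if (s %in% frame_at) frames[[length(frames) + 1]] <- xyz
  }
  frames
}
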