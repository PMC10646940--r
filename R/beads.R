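#' Bead specification
#'
#' A bead is a coarse-grained pseudo-atom. Five classes are used throughout:
#' `a` (ditopic binder), `c` (ditopic centre), `b` (polytopic binder),
#' `n` (tritopic centre) and `m` (tetratopic centre). Each bead carries an
#' equilibrium bond radius `bond_r` (the per-bead half of the Lorentz
#' mixing rule), an excluded-volume size `sigma` and strength `epsilon`.
#'
#' @param class_label one of `"a"`, `"b"`, `"c"`, `"m"`, `"n"`.
#' @param bond_r equilibrium bond radius in Angstrom (> 0).
#' @param sigma excluded-volume size in Angstrom (> 0); default 1.
#' @param epsilon excluded-volume strength in kJ/mol (>= 0); default 10.
#' @return an object of class `bead_spec`.
#' @examples
#' bead_spec("a", bond_r = 2)
#' @export
bead_spec <- function(class_label, bond_r = 2, sigma = 1, epsilon = 10) {
  if (!class_label %in% c("a", "b", "c", "m", "n")) {
    abort("class_label must be one of a, b, c, m, n")
  }
  if (bond_r <= 0 || sigma <= 0 || epsilon < 0) {
    abort("bead_spec requires bond_r > 0, sigma > 0, epsilon >= 0")
  }
  structure(
    list(class_label = class_label, bond_r = bond_r,
         sigma = sigma, epsilon = epsilon),
    class = "bead_spec"
  )
}

#' @exportS3Method base::print
print.bead_spec <- function(x, ...) {
  cat(sprintf("<bead %s> bond_r = %g A, sigma = %g A, epsilon = %g kJ/mol\n",
              x$class_label, x$bond_r, x$sigma, x$epsilon))
  invisible(x)
}

#' Lorentz mixing rule for equilibrium bond lengths
#'
#' The equilibrium length of a bond between bead types i and j is the
#' arithmetic mean of their bond radii.
#'
#' @param ri,rj bond radii (Angstrom) of the two bead types.
#' @return equilibrium bond length in Angstrom.
#' @export
mix_r0 <- function(ri, rj) (ri + rj) / 2

#' Ditopic bite angle
#'
#' The bite angle of a ditopic building block is the angle between its two
#' binding vectors, `theta_bite = 2 * (theta0 - 90)`, where `theta0` is the
#' target internal b-a-c angle on both sides. The relation assumes a straight
#' a-c-a backbone and a b-a-a-b torsion near zero (preorganised ligand).
#'
#' @param theta0 target internal b-a-c angle in degrees, in `[90, 180]`.
#' @return bite angle in degrees.
#' @examples
#' bite_angle(135) # 90
#' @export
bite_angle <- function(theta0) {
  if (any(theta0 < 90 | theta0 > 180)) {
    abort("theta0 must lie in [90, 180] degrees")
  }
  2 * (theta0 - 90)
}

new_building_block <- function(beads, xyz, binder_idx, centre_idx, bonds,
                               angles, arity, bac_angle = NA_real_) {
  structure(
    list(beads = beads, xyz = xyz, binder_idx = binder_idx,
         centre_idx = centre_idx, bonds = bonds, angles = angles,
         arity = arity, bac_angle = bac_angle),
    class = "building_block"
  )
}

#' @exportS3Method base::print
print.building_block <- function(x, ...) {
  cat(sprintf("<building_block> arity %d, %d beads (%s)\n",
              x$arity, nrow(x$beads), paste(x$beads$class, collapse = "-")))
  invisible(x)
}

beads_table <- function(specs) {
  tibble(
    class = vapply(specs, function(s) s$class_label, character(1)),
    bond_r = vapply(specs, function(s) s$bond_r, numeric(1)),
    sigma = vapply(specs, function(s) s$sigma, numeric(1)),
    epsilon = vapply(specs, function(s) s$epsilon, numeric(1))
  )
}

#' Construct a ditopic (linear) building block
#'
#' Three beads a-c-a, collinear along x at the mixing-rule spacing. The two
#' `a` beads are the binders. The backbone carries an internal a-c-a angle
#' term at 180 degrees (the bite-angle picture assumes a straight backbone);
#' the target b-a-c angle `bac_angle` is stored and applied at assembly time,
#' when the partner `b` bead exists.
#'
#' @param bac_angle target internal b-a-c angle in degrees (90-180).
#' @param bead_a,bead_c [bead_spec()]s for the binder and centre beads.
#' @param backbone_angle internal a-c-a target in degrees; default 180.
#' @return a `building_block` with zero internal strain.
#' @examples
#' di <- make_ditopic(135)
#' bite_angle(di$bac_angle)
#' @export
make_ditopic <- function(bac_angle,
                         bead_a = bead_spec("a"),
                         bead_c = bead_spec("c"),
                         backbone_angle = 180) {
  if (bac_angle < 90 || bac_angle > 180) {
    abort("bac_angle must lie in [90, 180] degrees")
  }
  r0 <- mix_r0(bead_a$bond_r, bead_c$bond_r)
  xyz <- rbind(c(-r0, 0, 0), c(0, 0, 0), c(r0, 0, 0))
  new_building_block(
    beads = beads_table(list(bead_a, bead_c, bead_a)),
    xyz = xyz,
    binder_idx = c(1L, 3L),
    centre_idx = 2L,
    bonds = tibble(i = c(1L, 2L), j = c(2L, 3L), r0 = r0),
    angles = tibble(i = 1L, j = 2L, k = 3L, theta0 = backbone_angle),
    arity = 2L,
    bac_angle = bac_angle
  )
}

# polar cone angle (degrees) giving pairwise bnb angle theta for 3 binders
tritopic_cone_angle <- function(theta) {
  rad2deg(acos(sqrt((2 * cos(deg2rad(theta)) + 1) / 3)))
}

# polar cone angle (degrees) giving adjacent bmb angle theta for 4 binders
tetratopic_cone_angle <- function(theta) {
  rad2deg(acos(sqrt(cos(deg2rad(theta)))))
}

cone_points <- function(alpha_deg, azimuths_deg, r) {
  al <- deg2rad(alpha_deg)
  t(vapply(deg2rad(azimuths_deg), function(az) {
    r * c(sin(al) * cos(az), sin(al) * sin(az), cos(al))
  }, numeric(3)))
}

#' Construct a tritopic building block
#'
#' Centre bead `n` at the origin with three `b` binder beads on a cone about
#' +z (azimuths 0, 120, 240 degrees) at the polar angle that makes all three
#' pairwise b-n-b angles equal to `bnb_angle`:
#' `alpha = acos(sqrt((2 cos(theta) + 1) / 3))`. `bnb_angle = 120` is the
#' planar limit.
#'
#' @param bnb_angle target b-n-b angle in degrees, in `(0, 120]`.
#' @param bead_n,bead_b [bead_spec()]s for the centre and binder beads.
#' @return a `building_block` with zero internal strain.
#' @export
make_tritopic <- function(bnb_angle,
                          bead_n = bead_spec("n"),
                          bead_b = bead_spec("b")) {
  if (bnb_angle <= 0 || bnb_angle > 120) {
    abort("bnb_angle must lie in (0, 120] degrees (120 = planar)")
  }
  r0 <- mix_r0(bead_n$bond_r, bead_b$bond_r)
  alpha <- tritopic_cone_angle(bnb_angle)
  xyz <- rbind(c(0, 0, 0), cone_points(alpha, c(0, 120, 240), r0))
  new_building_block(
    beads = beads_table(list(bead_n, bead_b, bead_b, bead_b)),
    xyz = xyz,
    binder_idx = 2:4,
    centre_idx = 1L,
    bonds = tibble(i = 1L, j = 2:4, r0 = r0),
    angles = tibble(i = c(2L, 2L, 3L), j = 1L, k = c(3L, 4L, 4L),
                    theta0 = bnb_angle),
    arity = 3L
  )
}

#' Construct a tetratopic building block
#'
#' Centre bead `m` at the origin with four `b` binder beads on a cone about
#' +z (azimuths 0, 90, 180, 270 degrees) at polar angle
#' `alpha = acos(sqrt(cos(theta)))`, which makes the four adjacent b-m-b
#' angles equal `bmb_angle` and the two opposite angles `2 * alpha`.
#' `bmb_angle = 90` is the square-planar limit (opposite angle 180).
#'
#' @param bmb_angle target adjacent b-m-b angle in degrees, in `(0, 90]`.
#' @param bead_m,bead_b [bead_spec()]s for the centre and binder beads.
#' @return a `building_block` with zero internal strain.
#' @export
make_tetratopic <- function(bmb_angle,
                            bead_m = bead_spec("m"),
                            bead_b = bead_spec("b")) {
  if (bmb_angle <= 0 || bmb_angle > 90) {
    abort("bmb_angle must lie in (0, 90] degrees (90 = square planar)")
  }
  r0 <- mix_r0(bead_m$bond_r, bead_b$bond_r)
  alpha <- tetratopic_cone_angle(bmb_angle)
  xyz <- rbind(c(0, 0, 0), cone_points(alpha, c(0, 90, 180, 270), r0))
  new_building_block(
    beads = beads_table(list(bead_m, bead_b, bead_b, bead_b, bead_b)),
    xyz = xyz,
    binder_idx = 2:5,
    centre_idx = 1L,
    bonds = tibble(i = 1L, j = 2:5, r0 = r0),
    angles = tibble(
      i = c(2L, 3L, 4L, 2L, 2L, 3L),
      j = 1L,
      k = c(3L, 4L, 5L, 5L, 4L, 5L),
      theta0 = c(rep(bmb_angle, 4), rep(2 * alpha, 2))
    ),
    arity = 4L
  )
}
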