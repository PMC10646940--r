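# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: angles/dihedrals are measured directly from
# coordinates, gradients by central finite differences, and the shape
# measure by exhaustive permutation enumeration.

oracle_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oracle_fd_gradient <- function(cage, xyz = cage$xyz, h = 1e-5) {
  fd <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) {
    for (q in 1:3) {
      xp <- xyz; xp[i, q] <- xp[i, q] + h
      xm <- xyz; xm[i, q] <- xm[i, q] - h
      fd[i, q] <- (cage_energy(cage, xp)$E_total -
                     cage_energy(cage, xm)$E_total) / (2 * h)
    }
  }
  fd
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive continuous shape measure: every permutation, closed-form
# superposition per permutation
oracle_cshm <- function(points, ref_xyz) {
  p <- sweep(points, 2, colMeans(points))
  q <- sweep(ref_xyz, 2, colMeans(ref_xyz))
  pn <- sum(p^2); qn <- sum(q^2)
  best <- Inf
  perms <- all_permutations(nrow(p))
  for (r in seq_len(nrow(perms))) {
    s <- svd(t(q) %*% p[perms[r, ], , drop = FALSE])
    d <- s$d
    d[3] <- d[3] * sign(det(s$u) * det(s$v))
    val <- 100 * (1 - sum(d)^2 / (pn * qn))
    if (val < best) best <- val
  }
  max(0, best)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  r <- qr.Q(qr(m))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# a small strained cage used in several energy tests
strained_test_cage <- function(torsion = "on") {
  build_cage("Tri2Di3", list(make_tritopic(100), make_ditopic(120)),
             torsion = torsion)
}
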