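# Shared fixtures: random topography specs, tolerance helpers, and the
# independent brute-force oracles used against the closed-form routes.

rel_err <- function(x, ref) abs(x - ref) / max(abs(ref), 1e-12)

# fold a heading onto [0, pi/2]: headings related by reflections of the
# branching axes describe congruent cones
fold_heading <- function(h) {
  h <- abs(((h + pi) %% (2 * pi)) - pi)
  ifelse(h > pi / 2, pi - h, h)
}

rand_spec <- function(pitch_rng = c(0.5, 2), asym_rng = c(0, 0.95),
                      tilt_rng = c(0, 2)) {
  topography_spec(runif(1, pitch_rng[1], pitch_rng[2]),
                  runif(1, asym_rng[1], asym_rng[2]),
                  runif(1, tilt_rng[1], tilt_rng[2]),
                  runif(1, 0, 2 * pi))
}

rotation_from_vec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  a <- cos(th / 2); b <- sin(th / 2) * v / th
  q <- c(a, b)
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

# brute-force minimum RMSD over rigid motions: hierarchically refined grid
# over the quaternion (axis-angle) parameterization of SO(3); entirely
# independent of the Kabsch construction
brute_force_rmsd <- function(ca, cb, levels = 14L) {
  A <- sweep(ca, 2, colMeans(ca))
  B <- sweep(cb, 2, colMeans(cb))
  n <- nrow(A)
  rmsd_of <- function(v) {
    R <- rotation_from_vec(v)
    sqrt(sum((B %*% t(R) - A)^2) / n)
  }
  best_v <- c(0, 0, 0)
  best <- rmsd_of(best_v)
  gpts <- seq(-1, 1, length.out = 13L)
  for (x in pi * gpts) for (y in pi * gpts) for (z in pi * gpts) {
    r <- rmsd_of(c(x, y, z))
    if (r < best) { best <- r; best_v <- c(x, y, z) }
  }
  w <- 0.6
  gpts <- seq(-1, 1, length.out = 9L)
  for (lev in seq_len(levels)) {
    centre <- best_v
    for (x in w * gpts) for (y in w * gpts) for (z in w * gpts) {
      v <- centre + c(x, y, z)
      r <- rmsd_of(v)
      if (r < best) { best <- r; best_v <- v }
    }
    w <- w / 2
  }
  best
}

rand_geometry <- function(n = 6L, label = "g") {
  elems <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
  geometry(elems, matrix(rnorm(3 * n), n, 3), label)
}

# rigid-motion copy of a geometry (proper rotation + translation)
rigid_copy <- function(g, v = NULL, t = NULL, label = g$label) {
  if (is.null(v)) v <- runif(3, -pi, pi)
  if (is.null(t)) t <- rnorm(3)
  R <- rotation_from_vec(v)
  geometry(g$elements, g$coords %*% t(R) + rep(t, each = nrow(g$coords)),
           label)
}

# butane-like 6-atom chain whose 1-2-3-4 torsion is `angle_deg`; atoms 5, 6
# are off-chain markers so superposition is non-degenerate
chain_with_torsion <- function(angle_deg, label = sprintf("t%03d", angle_deg)) {
  a <- angle_deg * pi / 180
  coords <- rbind(c(cos(a) * 1.2, sin(a) * 1.2, -1),
                  c(0, 0, -1), c(0, 0, 0.5), c(1.2, 0, 0.9),
                  c(-0.9, 0.7, -1.6), c(1.4, -0.8, 1.9))
  geometry(c("C", "C", "C", "C", "H", "H"), coords, label)
}
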