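# Canonical branching vectors, topography parameters, P/B classification
# and the brute-force classification oracle.

test_that("canonicalization fixes orthogonal input and undoes state mixing", {
  g <- c(2, 0, 0); h <- c(0, 1, 0); s <- c(0.4, 0.1, 0)
  bs <- canonical_branching(g, h, s)
  expect_identical(bs$rotation_angle, 0)
  expect_identical(bs$g_can, g)
  expect_identical(bs$h_can, h)

  set.seed(13)
  for (i in 1:25) {
    beta <- runif(1, -pi / 2, pi / 2)
    gm <- cos(2 * beta) * g + sin(2 * beta) * h
    hm <- -sin(2 * beta) * g + cos(2 * beta) * h
    bs2 <- canonical_branching(gm, hm, s)
    # recovered up to swap/sign: same norms, same plane, orthogonal
    expect_equal(sort(c(sqrt(sum(bs2$g_can^2)), sqrt(sum(bs2$h_can^2)))),
                 c(1, 2), tolerance = 1e-12)
    expect_lt(abs(sum(bs2$g_can * bs2$h_can)), 1e-10 * 2)
    expect_equal(abs(bs2$g_can[1:2] / sqrt(sum(bs2$g_can^2))), c(1, 0),
                 tolerance = 1e-10)
  }
})

test_that("canonicalization orthogonalizes random pairs and is idempotent", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    g <- rnorm(n); h <- rnorm(n); s <- rnorm(n)
    bs <- canonical_branching(g, h, s)
    gn <- sqrt(sum(bs$g_can^2)); hn <- sqrt(sum(bs$h_can^2))
    expect_lte(abs(sum(bs$g_can * bs$h_can)), 1e-10 * gn * hn)
    expect_gte(gn, hn)
    bs2 <- canonical_branching(bs$g_can, bs$h_can, bs$s_vec)
    expect_equal(bs2$rotation_angle, 0, tolerance = 1e-12)
    expect_equal(bs2$g_can, bs$g_can, tolerance = 1e-12)
  }
})

test_that("extraction refuses points that are not degenerate", {
  m <- build_model(topography_spec(1, 0.4, 0.5, 1), n_dim = 2)
  ev <- adiabatic_eval(m, c(0.3, 0.2))
  expect_error(extract_branching_vectors(ev), "not a degeneracy")
})

test_that("topography parameters follow the closed forms", {
  # zero tilt: P = 0, heading 0 by convention, peaked side
  tp0 <- compute_topography(canonical_branching(c(1.5, 0), c(0, 1), c(0, 0)))
  expect_identical(tp0$tilt_magnitude, 0)
  expect_identical(tp0$tilt_heading, 0)
  expect_identical(tp0$p_value, 0)

  # circular cone: asymmetry 0
  tpc <- compute_topography(canonical_branching(c(1, 0), c(0, 1), c(0, 0)))
  expect_identical(tpc$asymmetry, 0)
  expect_true("circular" %in% tpc$flags)

  # worked case g = (2,0), h = (0,1), s = (0.5,0)
  tp <- compute_topography(canonical_branching(c(2, 0), c(0, 1), c(0.5, 0)))
  expect_equal(tp$asymmetry, 0.6)
  expect_equal(tp$pitch, sqrt(2.5))
  cl <- classify(tp)
  bf <- brute_force_classify(tp)
  expect_identical(cl$vertical, bf$vertical)
  expect_identical(cl$lateral, bf$lateral)

  expect_error(compute_topography(canonical_branching(c(0, 0), c(0, 0),
                                                      c(1, 0))),
               "degenerate cone")
  expect_warning(compute_topography(canonical_branching(c(1, 0), c(0, 1e-7),
                                                        c(0.3, 0))),
                 "asymmetry")
})

test_that("classification follows the P/B quadrants with boundary flags", {
  mk <- function(p, b) list(p_value = p, b_value = b)
  c1 <- classify(mk(0.5, 0.5))
  expect_identical(c(c1$vertical, c1$lateral), c("peaked", "bifurcating"))
  # borderline single-path just above 1 stays peaked/single_path
  c2 <- classify(mk(0.7, 1.01))
  expect_identical(c(c2$vertical, c2$lateral), c("peaked", "single_path"))
  expect_true("b_boundary" %in% c2$boundary_flags)
  c3 <- classify(mk(1.0, 0.3), epsilon = 0.02)
  expect_identical(c3$boundary_flags, "p_boundary")
  c4 <- classify(mk(1.5, 2))
  expect_identical(c(c4$vertical, c4$lateral), c("sloped", "single_path"))
  expect_length(c4$boundary_flags, 0)
})

test_that("surface grids reproduce the first-order cone", {
  tp <- compute_topography(canonical_branching(c(1.2, 0), c(0, 0.9),
                                               c(0.3, 0.2)))
  gr <- surface_grid(tp, radii = c(0, 0.5, 1), angles = seq(0, 2 * pi, 0.3),
                     e_x = -0.1)
  expect_equal(gr$lower[1, ], gr$upper[1, ])          # degenerate apex
  expect_equal(unique(gr$lower[1, ]), -0.1)
  gap1 <- gr$upper[2, ] - gr$lower[2, ]
  gap2 <- gr$upper[3, ] - gr$lower[3, ]
  expect_equal(gap2 / gap1, rep(2, length(gap1)))     # linear in r

  sym <- compute_topography(canonical_branching(c(1, 0), c(0, 1), c(0, 0)))
  gs <- surface_grid(sym, radii = c(0.4), angles = seq(0, 2 * pi, 0.1))
  expect_lt(diff(range(gs$lower)), 1e-14)             # theta-independent
})

test_that("brute-force scan flags inconclusive symmetric cases", {
  m <- build_model(topography_spec(1, 0, 0, 0), n_dim = 2)  # circular, untilted
  bf <- brute_force_classify(m)
  expect_true("inconclusive" %in% bf$boundary_flags)
  # strongly tilted cone is sloped by direct inspection
  ms <- build_model(topography_spec(1, 0.3, 5, 1.1), n_dim = 2)
  expect_identical(brute_force_classify(ms)$vertical, "sloped")
})

test_that("P/B are gauge and frame invariant and scale correctly", {
  set.seed(29)
  for (i in 1:15) {
    sp <- rand_spec(asym_rng = c(0.05, 0.95), tilt_rng = c(0.1, 2))
    m <- build_model(sp, n_dim = 3, seed = i)
    tp <- characterize_model(m)
    ev <- adiabatic_eval(m, numeric(3))
    g <- ev$grad_diff_half; h <- ev$coupling_grad; s <- ev$grad_mean

    beta <- runif(1, -1, 1)
    gm <- cos(2 * beta) * g + sin(2 * beta) * h
    hm <- -sin(2 * beta) * g + cos(2 * beta) * h
    tp_mix <- compute_topography(canonical_branching(gm, hm, s))
    expect_lt(rel_err(tp_mix$p_value, tp$p_value), 1e-10)
    expect_lt(rel_err(tp_mix$b_value, tp$b_value), 1e-10)

    U <- rotation_from_vec(runif(3, -pi, pi))
    tp_rot <- compute_topography(canonical_branching(drop(U %*% g),
                                                     drop(U %*% h),
                                                     drop(U %*% s)))
    expect_lt(rel_err(tp_rot$p_value, tp$p_value), 1e-10)
    expect_lt(rel_err(tp_rot$b_value, tp$b_value), 1e-10)

    k <- runif(1, 0.2, 5)   # common scaling of all gradients
    tp_sc <- compute_topography(canonical_branching(k * g, k * h, k * s))
    expect_lt(rel_err(tp_sc$pitch, k * tp$pitch), 1e-12)
    expect_lt(rel_err(tp_sc$asymmetry, tp$asymmetry), 1e-12)
    expect_lt(rel_err(tp_sc$tilt_magnitude, tp$tilt_magnitude), 1e-12)
    expect_lt(rel_err(tp_sc$p_value, tp$p_value), 1e-12)
    expect_lt(rel_err(tp_sc$b_value, tp$b_value), 1e-12)
  }
})

test_that("closed-form classification agrees with the direct scan", {
  set.seed(37)
  n_cmp <- 0L
  while (n_cmp < 60L) {
    sp <- rand_spec(asym_rng = c(0.02, 0.95))
    m <- build_model(sp, n_dim = 2, seed = n_cmp + 1L)
    tp <- characterize_model(m)
    if (abs(tp$p_value - 1) <= 0.05 || abs(tp$b_value - 1) <= 0.05) next
    n_cmp <- n_cmp + 1L
    cl <- classify(tp)
    bf <- brute_force_classify(m)
    expect_false("inconclusive" %in% bf$boundary_flags)
    expect_identical(cl$vertical, bf$vertical)
    expect_identical(cl$lateral, bf$lateral)
  }
})
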