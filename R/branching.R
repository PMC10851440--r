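## Branching-space analysis of a conical intersection.
##
## At a two-state degeneracy the local first-order shape of the two
## adiabatic sheets is set by three vectors: g (half the gradient of the
## energy difference), h (the coupling gradient) and s (the mean gradient).
## In the orthogonalized canonical gauge, with scaled branching-plane
## coordinates (x along g, y along h),
##
##   E+-(x, y) = E_X + delta_gh * [ sigma_x x + sigma_y y
##                                  +- sqrt((1 + Delta) x^2 + (1 - Delta) y^2) ]
##
## where delta_gh = sqrt((|g|^2 + |h|^2)/2) is the pitch, Delta in [0, 1)
## the asymmetry, and (sigma_x, sigma_y) the relative tilt of magnitude
## sigma at heading theta_s.  Two dimensionless discriminants classify the
## intersection:
##
##   P = sigma^2 (1 - Delta cos 2 theta_s) / (1 - Delta^2)
##   B = [ (sigma_x^2 (1 + Delta))^(1/3) + (sigma_y^2 (1 - Delta))^(1/3) ]
##       / (2 Delta)^(2/3)
##
## P < 1: peaked (the lower sheet falls away from the apex in every
## branching-plane direction); P > 1: sloped.  B < 1: bifurcating (steepest
## descent splits into two valleys along the +-g axis); B > 1: single path.

#' Orthogonalize branching-space vectors at a degenerate point
#'
#' The raw half-gradient-difference and coupling-gradient vectors at a
#' conical intersection depend on the arbitrary unitary mixing of the two
#' degenerate states: mixing the states by an angle beta rotates the (g, h)
#' pair by 2*beta.  This operation applies the unique mixing rotation that
#' makes the returned vectors orthogonal with `|g_can| >= |h_can|`
#' (canonical gauge); all topography parameters computed downstream are
#' therefore gauge invariant.
#'
#' @param point Degenerate-point data: either the result of
#'   [adiabatic_eval()] at a (near-)degenerate coordinate, or a list with
#'   fields `grad_lower`, `grad_upper`, `coupling_grad` and `gap` (gap in
#'   Hartree; the coupling gradient is the gap-scaled coupling, finite at
#'   the degeneracy).
#' @param gap_tol Maximum gap (Hartree) accepted as a degeneracy.
#' @return A `branching_space` object with fields `g_can`, `h_can`, `s_vec`
#'   and `rotation_angle` (the state-mixing angle beta applied, radians).
#' @export
extract_branching_vectors <- function(point, gap_tol = 1e-5) {
  if (!is.null(point$gap) && point$gap > gap_tol)
    stop("not a degeneracy: gap = ", format(point$gap),
         " Hartree exceeds gap_tol = ", format(gap_tol))
  g_raw <- if (!is.null(point$grad_diff_half) && isTRUE(point$degenerate))
    point$grad_diff_half else (point$grad_upper - point$grad_lower) / 2
  h_raw <- point$coupling_grad
  s_vec <- (point$grad_upper + point$grad_lower) / 2
  canonical_branching(g_raw, h_raw, s_vec)
}

#' Canonicalize raw branching vectors directly
#'
#' Rotates a raw (g, h) pair by the state-mixing angle
#' `beta = atan2(2 g.h, |g|^2 - |h|^2)/4`, which simultaneously zeroes
#' `g.h` and enforces `|g_can| >= |h_can|`; an already canonical pair maps
#' to itself (`rotation_angle = 0`), including the circular tie
#' `|g| = |h|`.
#'
#' @param g_raw,h_raw Raw half-gradient-difference and coupling-gradient
#'   vectors (any mutual gauge).
#' @param s_vec Mean-gradient vector.
#' @return A `branching_space` object; see [extract_branching_vectors()].
#' @export
canonical_branching <- function(g_raw, h_raw, s_vec) {
  A <- sum(g_raw^2) - sum(h_raw^2)
  B <- 2 * sum(g_raw * h_raw)
  beta <- atan2(B, A) / 4
  cb <- cos(2 * beta); sb <- sin(2 * beta)
  g_can <- cb * g_raw + sb * h_raw
  h_can <- -sb * g_raw + cb * h_raw
  structure(list(g_can = g_can, h_can = h_can, s_vec = s_vec,
                 rotation_angle = beta),
            class = "branching_space")
}

#' @export
print.branching_space <- function(x, ...) {
  cat(sprintf("Branching space: |g| = %.6g, |h| = %.6g Ha/Bohr (beta = %.4g rad)\n",
              sqrt(sum(x$g_can^2)), sqrt(sum(x$h_can^2)), x$rotation_angle))
  invisible(x)
}

#' Compute topography parameters from canonical branching vectors
#'
#' Derives the pitch, asymmetry, relative tilt and tilt heading from the
#' canonical g/h/s vectors, together with the two classification
#' discriminants P (peaked/sloped) and B (bifurcating/single-path); see the
#' package vignette for the formulas.  The tilt is the component of the
#' mean gradient resolved in the branching plane.
#'
#' @param bs A `branching_space` from [extract_branching_vectors()].
#' @return A `topography_params` object with fields `pitch`, `asymmetry`,
#'   `tilt_magnitude`, `tilt_heading`, `p_value`, `b_value` and a
#'   `flags` character vector (contains `"circular"` when the cone is
#'   rotationally symmetric and `"near_seam_degenerate"` when `|h| ~ 0`,
#'   i.e. asymmetry ~ 1, where B becomes ill-conditioned).
#' @export
#' @examples
#' bs <- canonical_branching(c(2, 0), c(0, 1), c(0.5, 0))
#' tp <- compute_topography(bs)
#' tp$asymmetry   # 0.6
compute_topography <- function(bs) {
  g2 <- sum(bs$g_can^2); h2 <- sum(bs$h_can^2)
  if (g2 <= 0) stop("degenerate cone: |g_can| = 0")
  pitch <- sqrt((g2 + h2) / 2)
  delta <- (g2 - h2) / (g2 + h2)
  flags <- character()
  if (delta > 1 - 1e-9) {
    warning("asymmetry ~ 1 (|h| ~ 0): B discriminant ill-conditioned")
    flags <- c(flags, "near_seam_degenerate")
  }
  xhat <- bs$g_can / sqrt(g2)
  yhat <- if (h2 > 0) bs$h_can / sqrt(h2) else rep(0, length(bs$g_can))
  sx <- sum(bs$s_vec * xhat) / pitch
  sy <- sum(bs$s_vec * yhat) / pitch
  sigma <- sqrt(sx^2 + sy^2)
  heading <- if (sigma > 0) atan2(sy, sx) %% (2 * pi) else 0
  if (sigma == 0) {
    p_val <- 0
    b_val <- 0
    if (delta < 1e-12) flags <- c(flags, "circular")
  } else {
    p_val <- sigma^2 * (1 - delta * cos(2 * heading)) / (1 - delta^2)
    b_val <- ((sx^2 * (1 + delta))^(1 / 3) + (sy^2 * (1 - delta))^(1 / 3)) /
      (2 * delta)^(2 / 3)   # Inf for a tilted circular cone: single path
    if (delta < 1e-12) flags <- c(flags, "circular")
  }
  structure(list(pitch = pitch, asymmetry = delta,
                 tilt_magnitude = sigma, tilt_heading = heading,
                 p_value = p_val, b_value = b_val, flags = flags),
            class = "topography_params")
}

#' @export
print.topography_params <- function(x, ...) {
  cat(sprintf(
    "CI topography: pitch %.5g Ha/Bohr, asymmetry %.4f, tilt %.4f @ %.3f rad\n",
    x$pitch, x$asymmetry, x$tilt_magnitude, x$tilt_heading))
  cat(sprintf("  P = %.5g (%s)   B = %.5g (%s)\n",
              x$p_value, if (x$p_value < 1) "peaked" else "sloped",
              x$b_value, if (x$b_value < 1) "bifurcating" else "single path"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a conical intersection from its P and B discriminants
#'
#' Assigns the vertical class (`peaked` if P < 1, else `sloped`) and the
#' lateral class (`bifurcating` if B < 1, else `single_path`), flagging
#' values within `epsilon` of the unit boundary: borderline intersections
#' are common in practice and the flag keeps them visible in quadrant
#' tables.
#'
#' @param tp A `topography_params` object (or any list with `p_value`,
#'   `b_value`).
#' @param epsilon Boundary tolerance on |P - 1| and |B - 1|.
#' @return A `topography_class` object with `vertical`, `lateral` and
#'   `boundary_flags` (subset of `"p_boundary"`, `"b_boundary"`).
#' @export
classify <- function(tp, epsilon = 0.02) {
  if (!is.finite(tp$p_value) && !is.infinite(tp$p_value))
    stop("p_value must be finite")
  flags <- character()
  if (is.finite(tp$p_value) && abs(tp$p_value - 1) <= epsilon)
    flags <- c(flags, "p_boundary")
  if (is.finite(tp$b_value) && abs(tp$b_value - 1) <= epsilon)
    flags <- c(flags, "b_boundary")
  structure(list(
    vertical = if (tp$p_value < 1) "peaked" else "sloped",
    lateral = if (tp$b_value < 1) "bifurcating" else "single_path",
    boundary_flags = flags), class = "topography_class")
}

#' @export
print.topography_class <- function(x, ...) {
  cat(x$vertical, "/", x$lateral)
  if (length(x$boundary_flags))
    cat("  [", paste(x$boundary_flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Quadrant label of a classification
#'
#' @param cl A `topography_class`.
#' @return Single string, e.g. `"peaked/bifurcating"`.
#' @export
quadrant_label <- function(cl) paste(cl$vertical, cl$lateral, sep = "/")

#' First-order model surfaces over the branching plane
#'
#' Evaluates the two first-order sheets implied by a set of topography
#' parameters on a polar grid of the branching plane, for 3-D rendering of
#' the double cone.
#'
#' @param tp A `topography_params` object.
#' @param radii Non-negative radii (Bohr).
#' @param angles Angles (radians).
#' @param e_x Reference energy at the apex (Hartree).
#' @return List with matrices `lower`, `upper` (radii x angles), plus the
#'   `radii` and `angles` used.
#' @export
surface_grid <- function(tp, radii = seq(0, 1, length.out = 21),
                         angles = seq(0, 2 * pi, length.out = 73),
                         e_x = 0) {
  if (any(radii < 0)) stop("radii must be >= 0")
  sx <- tp$tilt_magnitude * cos(tp$tilt_heading)
  sy <- tp$tilt_magnitude * sin(tp$tilt_heading)
  tilt <- outer(radii, sx * cos(angles) + sy * sin(angles))
  cone <- outer(radii, sqrt(1 + tp$asymmetry * cos(2 * angles)))
  list(lower = e_x + tp$pitch * (tilt - cone),
       upper = e_x + tp$pitch * (tilt + cone),
       radii = radii, angles = angles)
}

#' Brute-force classification by direct inspection of the lower sheet
#'
#' Independent oracle for the P/B classification: scans the lower adiabatic
#' sheet on a circle of radius `radius` around the degeneracy and decides
#' the vertical class from whether the sheet lies below the apex energy in
#' every direction (peaked) or rises in some (sloped), and the lateral
#' class from the number of distinct local minima of the sheet around the
#' circle (2: bifurcating, 1: single path).  No use is made of the P/B
#' formulas.
#'
#' @param x Either a [two_state_model()] (scanned with [adiabatic_eval()]
#'   around the origin) or a `topography_params` object (scanned on its
#'   first-order surfaces).
#' @param radius Scan radius (Bohr); keep small relative to any curvature.
#' @param n_angles Number of angular samples on the circle.
#' @param tie_tol Relative tolerance below which angular variation is
#'   treated as a plateau and the scan declared inconclusive.
#' @return A `topography_class` whose `boundary_flags` contains
#'   `"inconclusive"` when the scan cannot decide at this resolution
#'   (plateaus, minima count outside {1, 2}); never a silent guess.
#' @export
brute_force_classify <- function(x, radius = 1e-3, n_angles = 1440L,
                                 tie_tol = 1e-9) {
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  if (inherits(x, "two_state_model")) {
    ev0 <- adiabatic_eval(x, numeric(x$n_dim))
    ## scan in the branching plane (span of the degenerate-pair vectors);
    ## plain Gram-Schmidt here, not the canonical gauge, keeps the oracle
    ## independent of the classification formulas
    u1 <- ev0$grad_diff_half / sqrt(sum(ev0$grad_diff_half^2))
    u2 <- ev0$coupling_grad - sum(ev0$coupling_grad * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
    f <- vapply(th, function(a) {
      q <- radius * (cos(a) * u1 + sin(a) * u2)
      adiabatic_eval(x, q)$e_lower
    }, numeric(1)) - ev0$e_lower
  } else {
    sx <- x$tilt_magnitude * cos(x$tilt_heading)
    sy <- x$tilt_magnitude * sin(x$tilt_heading)
    f <- radius * x$pitch *
      (sx * cos(th) + sy * sin(th) - sqrt(1 + x$asymmetry * cos(2 * th)))
  }
  spread <- max(f) - min(f)
  flags <- character()
  if (spread <= tie_tol * max(abs(f), 1e-300)) {
    ## rotationally symmetric within tolerance: no direction distinguished
    return(structure(list(vertical = if (max(f) < 0) "peaked" else "sloped",
                          lateral = "bifurcating",
                          boundary_flags = "inconclusive"),
                     class = "topography_class"))
  }
  vertical <- if (max(f) < 0) "peaked" else "sloped"
  prv <- c(f[n_angles], f[-n_angles])
  nxt <- c(f[-1L], f[1L])
  is_min <- f < prv & f < nxt
  n_min <- sum(is_min)
  if (any(f == prv) || n_min < 1L || n_min > 2L)
    flags <- c(flags, "inconclusive")
  lateral <- if (n_min >= 2L) "bifurcating" else "single_path"
  structure(list(vertical = vertical, lateral = lateral,
                 boundary_flags = flags), class = "topography_class")
}

#' Characterize a model's intersection at the origin
#'
#' Convenience composition: evaluate the model at its crossing, extract and
#' canonicalize the branching vectors, and compute topography parameters.
#' Two routes are available: `"analytic"` uses the model's closed-form
#' gradients; `"fd"` re-derives everything by central finite differences of
#' the adiabatic surfaces alone (the squared half-gap is differentiable at
#' the apex even though the gap is not, so its Hessian
#' \eqn{2(gg^T + hh^T)} yields the canonical vectors by eigendecomposition).
#' The finite-difference route treats the model as a black box and serves
#' as an independent check of the analytic path; its heading is recovered
#' only up to reflections of the branching axes (which leave the cone — and
#' P, B — unchanged) and is reported folded into `[0, pi/2]`.
#'
#' @param model A [two_state_model()].
#' @param method `"analytic"` or `"fd"`.
#' @param fd_step Displacement (Bohr) for the finite-difference route.
#' @return A `topography_params` object.
#' @export
characterize_model <- function(model, method = c("analytic", "fd"),
                               fd_step = 1e-3) {
  method <- match.arg(method)
  if (method == "analytic") {
    ev <- adiabatic_eval(model, numeric(model$n_dim))
    return(compute_topography(extract_branching_vectors(ev)))
  }
  n <- model$n_dim
  half_gap2 <- function(q) {
    ev <- adiabatic_eval(model, q, degeneracy_tol = 0)
    (ev$gap / 2)^2
  }
  mean_e <- function(q) adiabatic_eval(model, q, degeneracy_tol = 0)$mean_energy
  H <- matrix(0, n, n)
  s_fd <- numeric(n)
  e0 <- half_gap2(numeric(n))
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- fd_step
    H[i, i] <- (half_gap2(ei) + half_gap2(-ei) - 2 * e0) / fd_step^2
    s_fd[i] <- (mean_e(ei) - mean_e(-ei)) / (2 * fd_step)
    for (j in seq_len(i - 1L)) {
      ej <- numeric(n); ej[j] <- fd_step
      H[i, j] <- H[j, i] <-
        (half_gap2(ei + ej) - half_gap2(ei - ej) -
           half_gap2(-ei + ej) + half_gap2(-ei - ej)) / (4 * fd_step^2)
    }
  }
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  g_can <- sqrt(lam[1] / 2) * eig$vectors[, 1]
  h_can <- sqrt(lam[2] / 2) * eig$vectors[, 2]
  ## reflection gauge: orient each axis along the tilt so the folded heading
  ## lands in [0, pi/2]
  if (sum(s_fd * g_can) < 0) g_can <- -g_can
  if (sum(s_fd * h_can) < 0) h_can <- -h_can
  compute_topography(structure(list(g_can = g_can, h_can = h_can,
                                    s_vec = s_fd, rotation_angle = 0),
                               class = "branching_space"))
}
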