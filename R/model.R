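## Two-state diabatic model Hamiltonians with a built-in conical intersection.
##
## The diabatic matrix over coordinates q (Bohr, length n_dim) is
##
##   H11(q) = e_x + (s + g) . q + q' Q11 q / 2
##   H22(q) = e_x + (s - g) . q + q' Q22 q / 2
##   H12(q) = h . q + q' Q12 q / 2
##
## so the adiabatic surfaces are E+-(q) = m(q) +- sqrt(d(q)^2 + c(q)^2) with
## m = (H11 + H22)/2, d = (H11 - H22)/2 and c = H12.  The two states are
## exactly degenerate at the origin for any choice of g, h, s and quadratic
## terms; g is half the gradient of the energy difference, h the coupling
## gradient and s the mean gradient, i.e. the standard branching-space
## vectors of the first-order double cone.

#' Construct a two-state diabatic model Hamiltonian
#'
#' Low-level constructor; most users will call [build_model()], which lays
#' out the branching-space vectors from a topography specification.
#'
#' @param n_dim Coordinate dimension (>= 2).
#' @param e_x Energy at the crossing point (Hartree).
#' @param s_vec,g_vec,h_vec Mean-gradient, half-gradient-difference and
#'   coupling-gradient vectors, each of length `n_dim` (Hartree/Bohr).
#' @param quad_terms Optional list with symmetric `n_dim x n_dim` matrices
#'   `Q11`, `Q22`, `Q12` of quadratic coefficients (Hartree/Bohr^2); `NULL`
#'   means all zero.
#' @param seed Integer seed recorded with the model (provenance; also the
#'   stream used by constructors that draw random orientations).
#' @return An object of class `two_state_model`.
#' @export
two_state_model <- function(n_dim, e_x, s_vec, g_vec, h_vec,
                            quad_terms = NULL, seed = 0L) {
  n_dim <- as.integer(n_dim)
  if (n_dim < 2L) stop("n_dim must be >= 2")
  for (v in list(s_vec, g_vec, h_vec)) {
    if (length(v) != n_dim || !all(is.finite(v)))
      stop("s_vec, g_vec, h_vec must be finite vectors of length n_dim")
  }
  if (!is.null(quad_terms)) {
    if (!all(c("Q11", "Q22", "Q12") %in% names(quad_terms)))
      stop("quad_terms must contain Q11, Q22, Q12")
    quad_terms <- lapply(quad_terms[c("Q11", "Q22", "Q12")], function(Q) {
      Q <- as.matrix(Q)
      if (!all(dim(Q) == n_dim)) stop("quadratic terms must be n_dim x n_dim")
      (Q + t(Q)) / 2  # enforce symmetry of each diabatic element
    })
  }
  structure(
    list(n_dim = n_dim, e_x = as.double(e_x),
         s_vec = as.double(s_vec), g_vec = as.double(g_vec),
         h_vec = as.double(h_vec), quad_terms = quad_terms,
         seed = as.integer(seed)),
    class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Two-state diabatic model (", x$n_dim, " coordinates)\n", sep = "")
  cat(sprintf("  e_x = %.6f Ha   |g| = %.4g   |h| = %.4g   |s| = %.4g Ha/Bohr\n",
              x$e_x, sqrt(sum(x$g_vec^2)), sqrt(sum(x$h_vec^2)),
              sqrt(sum(x$s_vec^2))))
  cat("  quadratic terms:", if (is.null(x$quad_terms)) "none" else "present",
      "\n")
  invisible(x)
}

#' Topography specification for a model conical intersection
#'
#' @param pitch Cone steepness scale \eqn{\delta_{gh}} (Hartree/Bohr), > 0.
#' @param asymmetry Ellipticity \eqn{\Delta_{gh}} of the cone cross-section,
#'   in `[0, 1)`.
#' @param tilt_magnitude Relative tilt \eqn{\sigma} (dimensionless, >= 0):
#'   in-plane mean-gradient magnitude divided by the pitch.
#' @param tilt_heading Tilt heading \eqn{\theta_s} (radians, measured from
#'   the g axis).
#' @return A `topography_spec` list.
#' @export
topography_spec <- function(pitch, asymmetry = 0, tilt_magnitude = 0,
                            tilt_heading = 0) {
  if (!is.finite(pitch) || pitch <= 0) stop("pitch must be positive")
  if (!is.finite(asymmetry) || asymmetry < 0 || asymmetry >= 1)
    stop("asymmetry must lie in [0, 1)")
  if (!is.finite(tilt_magnitude) || tilt_magnitude < 0)
    stop("tilt_magnitude must be >= 0")
  structure(list(pitch = pitch, asymmetry = asymmetry,
                 tilt_magnitude = tilt_magnitude,
                 tilt_heading = tilt_heading %% (2 * pi)),
            class = "topography_spec")
}

#' Build a model with prescribed branching-space topography
#'
#' Lays the branching plane in the first two coordinates: the canonical g
#' vector along axis 1 with norm `pitch * sqrt(1 + asymmetry)`, the h vector
#' along axis 2 with norm `pitch * sqrt(1 - asymmetry)`, and the mean
#' gradient in-plane at the requested heading with magnitude
#' `tilt_magnitude * pitch`.  Coordinates beyond the first two carry no
#' linear coupling; they receive a small positive diagonal quadratic term
#' (`seam_curvature`) on both diabatic diagonals so that the intersection
#' seam is bound and minimum-energy crossing-point searches in `n_dim > 2`
#' are well posed.
#'
#' @param target A [topography_spec()] (or list with the same fields).
#' @param n_dim Coordinate dimension (>= 2).
#' @param e_x Energy at the crossing (Hartree).
#' @param seed Integer seed stored with the model and used when
#'   `orientation = "random"`.
#' @param orientation `"axis"` (default) keeps the branching plane on the
#'   first two coordinates; `"random"` applies a random global rotation to
#'   all vectors (and quadratic terms), giving a model with identical
#'   topography in a rotated frame.
#' @param seam_curvature Diagonal quadratic coefficient (Hartree/Bohr^2)
#'   applied to coordinates outside the branching plane; 0 disables it.
#' @return A [two_state_model()] whose exact topography parameters at the
#'   origin equal `target`.
#' @export
#' @examples
#' m <- build_model(topography_spec(1, 0.6, 0.32, 0), n_dim = 2)
#' adiabatic_eval(m, c(0, 0))$gap   # 0: degeneracy by construction
build_model <- function(target, n_dim = 2L, e_x = 0, seed = 1L,
                        orientation = c("axis", "random"),
                        seam_curvature = 0.05) {
  if (!inherits(target, "topography_spec"))
    target <- do.call(topography_spec, target[c("pitch", "asymmetry",
                                                "tilt_magnitude",
                                                "tilt_heading")])
  orientation <- match.arg(orientation)
  n_dim <- as.integer(n_dim)
  if (n_dim < 2L) stop("n_dim must be >= 2")

  g <- h <- s <- numeric(n_dim)
  g[1] <- target$pitch * sqrt(1 + target$asymmetry)
  h[2] <- target$pitch * sqrt(1 - target$asymmetry)
  s[1] <- target$tilt_magnitude * target$pitch * cos(target$tilt_heading)
  s[2] <- target$tilt_magnitude * target$pitch * sin(target$tilt_heading)

  quad <- NULL
  if (n_dim > 2L && seam_curvature > 0) {
    Q <- diag(c(0, 0, rep(seam_curvature, n_dim - 2L)), n_dim)
    quad <- list(Q11 = Q, Q22 = Q, Q12 = matrix(0, n_dim, n_dim))
  }

  if (orientation == "random") {
    U <- with_seed(seed, random_rotation(n_dim))
    g <- drop(U %*% g); h <- drop(U %*% h); s <- drop(U %*% s)
    if (!is.null(quad))
      quad <- lapply(quad, function(Q) U %*% Q %*% t(U))
  }
  two_state_model(n_dim, e_x, s, g, h, quad, seed)
}

## Haar-ish random proper rotation via QR of a Gaussian matrix.
random_rotation <- function(n) {
  qr_ <- qr(matrix(rnorm(n * n), n, n))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), n)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Diabatic pieces and their gradients at q: m, d, c and grad_m, grad_d,
## grad_c.  Exact for any q (the model is at most quadratic).
diabatic_parts <- function(model, q) {
  q <- as.double(q)
  if (length(q) != model$n_dim) stop("coordinate length must equal n_dim")
  m <- model$e_x + sum(model$s_vec * q)
  d <- sum(model$g_vec * q)
  cc <- sum(model$h_vec * q)
  gm <- model$s_vec; gd <- model$g_vec; gc <- model$h_vec
  if (!is.null(model$quad_terms)) {
    Qm <- (model$quad_terms$Q11 + model$quad_terms$Q22) / 2
    Qd <- (model$quad_terms$Q11 - model$quad_terms$Q22) / 2
    Qc <- model$quad_terms$Q12
    m <- m + sum(q * (Qm %*% q)) / 2
    d <- d + sum(q * (Qd %*% q)) / 2
    cc <- cc + sum(q * (Qc %*% q)) / 2
    gm <- gm + drop(Qm %*% q)
    gd <- gd + drop(Qd %*% q)
    gc <- gc + drop(Qc %*% q)
  }
  list(m = m, d = d, c = cc, grad_m = gm, grad_d = gd, grad_c = gc)
}

#' Evaluate the adiabatic surfaces of a two-state model
#'
#' Solves the 2x2 diabatic eigenproblem in closed form and returns energies,
#' analytic gradients and coupling information at a coordinate.
#'
#' Away from degeneracy `coupling` is the derivative-coupling vector
#' (magnitude diverging as 1/gap) and `coupling_grad` the gap-scaled,
#' always-finite coupling-gradient vector.  At (numerical) degeneracy the
#' derivative coupling is undefined; the result is flagged `degenerate` and
#' carries the degenerate-pair vectors instead: `grad_diff_half` (half
#' gradient difference, the g vector) and `coupling_grad` (the h vector),
#' with state gradients reported in the diabatic gauge.
#'
#' @param model A [two_state_model()].
#' @param q Coordinate vector (Bohr), length `n_dim`.
#' @param degeneracy_tol Gap (Hartree) below which the point is treated as
#'   degenerate.
#' @return List with `e_lower`, `e_upper`, `gap`, `mean_energy`,
#'   `grad_lower`, `grad_upper`, `grad_mean`, `grad_diff_half`,
#'   `coupling_grad`, `coupling` (NULL when degenerate) and `degenerate`.
#' @export
adiabatic_eval <- function(model, q, degeneracy_tol = 1e-8) {
  p <- diabatic_parts(model, q)
  rho <- sqrt(p$d^2 + p$c^2)
  out <- list(e_lower = p$m - rho, e_upper = p$m + rho, gap = 2 * rho,
              mean_energy = p$m, grad_mean = p$grad_m)
  if (rho < degeneracy_tol / 2) {
    out$degenerate <- TRUE
    out$grad_diff_half <- p$grad_d
    out$coupling_grad <- p$grad_c
    out$grad_lower <- p$grad_m - p$grad_d
    out$grad_upper <- p$grad_m + p$grad_d
    out$coupling <- NULL
  } else {
    u <- (p$d * p$grad_d + p$c * p$grad_c) / rho   # gradient of rho
    out$degenerate <- FALSE
    out$grad_lower <- p$grad_m - u
    out$grad_upper <- p$grad_m + u
    out$grad_diff_half <- u
    out$coupling_grad <- (p$d * p$grad_c - p$c * p$grad_d) / rho
    out$coupling <- (p$d * p$grad_c - p$c * p$grad_d) / (2 * rho^2)
  }
  out
}

#' Perturb a model's linear and quadratic coefficients
#'
#' Adds independent Gaussian jitter to each component of the g, h and s
#' vectors (and quadratic terms, if present), emulating the change of the
#' local Hamiltonian under a different level of theory.  The jitter standard
#' deviation for a vector is `jitter_scale` times its norm; a zero vector
#' (e.g. `s_vec` of an untilted model) is jittered relative to the model's
#' pitch so that ensembles around symmetric models still explore tilt.
#' The crossing at the origin is preserved exactly (all perturbed terms
#' still vanish there).
#'
#' @param model A [two_state_model()].
#' @param jitter_scale Relative jitter magnitude (>= 0); 0 returns an
#'   identical model.
#' @param seed Integer seed; the draw is deterministic given `(model, seed)`.
#' @return A new [two_state_model()].
#' @export
perturb_model <- function(model, jitter_scale, seed) {
  if (!is.finite(jitter_scale) || jitter_scale < 0)
    stop("jitter_scale must be >= 0")
  if (jitter_scale == 0) return(model)
  pitch <- sqrt((sum(model$g_vec^2) + sum(model$h_vec^2)) / 2)
  jitter_vec <- function(v) {
    ref <- sqrt(sum(v^2))
    if (ref == 0) ref <- pitch
    v + rnorm(length(v), sd = jitter_scale * ref)
  }
  with_seed(seed, {
    g <- jitter_vec(model$g_vec)
    h <- jitter_vec(model$h_vec)
    s <- jitter_vec(model$s_vec)
    quad <- model$quad_terms
    if (!is.null(quad)) {
      quad <- lapply(quad, function(Q) {
        ref <- sqrt(sum(Q^2))
        if (ref == 0) return(Q)
        E <- matrix(rnorm(length(Q), sd = jitter_scale * ref), nrow(Q))
        Q + (E + t(E)) / 2
      })
    }
    two_state_model(model$n_dim, model$e_x, s, g, h, quad, seed)
  })
}

#' Serialize a model to / from JSON
#'
#' The layout is versioned with a `"format"` key (`"citopo-model/1"`);
#' vectors are flat numeric arrays, quadratic terms row-major matrices.
#'
#' @param model A [two_state_model()].
#' @param path File path; for `model_to_json(NULL)` the JSON string is
#'   returned instead of written.
#' @return `model_to_json`: the path (or JSON string) invisibly;
#'   `model_from_json`: the reconstructed [two_state_model()].
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(format = "citopo-model/1",
              n_dim = model$n_dim, e_x = model$e_x,
              s_vec = model$s_vec, g_vec = model$g_vec, h_vec = model$h_vec,
              seed = model$seed)
  if (!is.null(model$quad_terms))
    obj$quad_terms <- lapply(model$quad_terms, function(Q)
      list(nrow = nrow(Q), data = as.double(t(Q))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "citopo-model/1")
    stop("not a citopo-model/1 record")
  quad <- NULL
  if (!is.null(obj$quad_terms))
    quad <- lapply(obj$quad_terms, function(Q)
      matrix(Q$data, Q$nrow, byrow = TRUE))
  two_state_model(obj$n_dim, obj$e_x, obj$s_vec, obj$g_vec, obj$h_vec,
                  quad, obj$seed)
}
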