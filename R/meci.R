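## Minimum-energy crossing-point optimizers on two-state model surfaces.
##
## Two independent algorithms are provided, mirroring the two families used
## in practice for locating conical intersections without explicit
## nonadiabatic couplings (penalty functions) and with them (branching-plane
## projection):
##
##  * optimize_penalty: minimize  F(q) = mean(q) + w * gap^2 / (gap + alpha),
##    a smoothed gap penalty whose weight w is escalated geometrically when
##    the gap stalls above tolerance.
##  * optimize_projection: composite-gradient steps combining a Newton-type
##    degeneracy-closing component along the gap gradient with the mean
##    gradient projected out of the current branching plane (seam sliding).
##
## Both return the same result contract and a full per-iteration trace.

default_meci_params <- function() {
  list(penalty_weight = 5, smoothing = 0.02,
       gap_tol = 1e-6, step_tol = 1e-6, max_iter = 500L)
}

new_optres <- function(q_star, gap, mean_energy, n_iter, converged, trace) {
  tr <- do.call(rbind, trace)
  colnames(tr) <- c("gap", "mean_energy", "step_norm")
  structure(list(q_star = q_star, gap = gap, mean_energy = mean_energy,
                 n_iterations = n_iter, converged = converged, trace = tr),
            class = "meci_optresult")
}

#' @export
print.meci_optresult <- function(x, ...) {
  cat(sprintf("MECI search: %s in %d iterations (gap %.3e Ha, <E> %.6f Ha)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$gap, x$mean_energy))
  invisible(x)
}

#' Locate a minimum-energy crossing point with a smoothed gap penalty
#'
#' Minimizes the mean adiabatic energy plus a smoothed gap penalty
#' `w * gap^2/(gap + alpha)`.  For each penalty weight `w` the objective is
#' minimized with BFGS (analytic gradients); whenever the stage minimum
#' still has a gap above `gap_tol`, the weight doubles (geometric
#' escalation), driving the iterate onto the intersection seam.  The
#' penalty derivative vanishes at zero gap, so the objective gradient is
#' continuous through the seam.
#'
#' @param model A [two_state_model()].
#' @param q0 Starting coordinate (Bohr).
#' @param params Optional list overriding any of `penalty_weight` (initial
#'   weight, Hartree^-1 scale), `smoothing` (alpha, Hartree), `gap_tol`
#'   (Hartree), `step_tol` (Bohr), `max_iter` (penalty stages).
#' @return A `meci_optresult` with `q_star`, `gap`, `mean_energy`,
#'   `n_iterations` (penalty stages run), `converged` and the per-stage
#'   `trace` (gap, mean energy, step norm).  Exhausting the iteration
#'   budget yields `converged = FALSE` with the trace intact; no error is
#'   raised.
#' @export
#' @examples
#' m <- build_model(topography_spec(1, 0.4, 0.3, 1), n_dim = 2)
#' r <- optimize_penalty(m, c(0.7, -0.7))
#' r$converged; sqrt(sum(r$q_star^2))  # back at the conical intersection
optimize_penalty <- function(model, q0, params = list()) {
  p <- modifyList(default_meci_params(), params)
  stopifnot(p$gap_tol > 0, p$step_tol > 0, p$smoothing > 0)
  alpha <- p$smoothing
  w <- p$penalty_weight

  eval_at <- function(q) adiabatic_eval(model, q, degeneracy_tol = 0)
  fn <- function(q) {
    ev <- eval_at(q)
    ev$mean_energy + w * ev$gap^2 / (ev$gap + alpha)
  }
  gr <- function(q) {
    ev <- eval_at(q)
    dpen <- if (ev$gap > 0)
      (ev$gap^2 + 2 * alpha * ev$gap) / (ev$gap + alpha)^2 else 0
    ev$grad_mean + w * dpen * 2 * ev$grad_diff_half
  }

  q <- as.double(q0)
  trace <- list()
  stage <- 0L
  converged <- FALSE
  max_stages <- min(p$max_iter, 80L)
  repeat {
    stage <- stage + 1L
    fit <- stats::optim(q, fn, gr, method = "BFGS",
                        control = list(maxit = 300L, reltol = 1e-15))
    step_norm <- sqrt(sum((fit$par - q)^2))
    q <- fit$par
    ev <- eval_at(q)
    trace[[stage]] <- c(ev$gap, ev$mean_energy, step_norm)
    if (ev$gap < p$gap_tol && step_norm < p$step_tol) {
      converged <- TRUE
      break
    }
    if (stage >= max_stages) break
    if (ev$gap >= p$gap_tol) w <- 2 * w
  }
  new_optres(q, ev$gap, ev$mean_energy, stage, converged, trace)
}

#' Locate a minimum-energy crossing point by branching-plane projection
#'
#' Composite-gradient algorithm: at each iterate the gap is first closed by
#' Newton steps along the gap gradient (degeneracy restoration), then the
#' mean energy is relaxed along its gradient projected out of the current
#' branching plane (the span of the gradient-difference and
#' coupling-gradient vectors), which to first order preserves the
#' degeneracy.  Below a gap of `1e-8` Hartree the degenerate-pair vectors
#' replace the derivative-coupling construction, avoiding the 1/gap
#' blow-up.
#'
#' @inheritParams optimize_penalty
#' @param params Optional list overriding `gap_tol`, `step_tol`, `max_iter`.
#' @return A `meci_optresult`; same contract as [optimize_penalty()].
#' @export
optimize_projection <- function(model, q0, params = list()) {
  p <- modifyList(default_meci_params(), params)
  stopifnot(p$gap_tol > 0, p$step_tol > 0)
  q <- as.double(q0)
  n <- model$n_dim
  trace <- list()
  iter <- 0L
  converged <- FALSE

  restore <- function(q) {
    ## Newton iteration on gap(q) = 0 along the gap gradient
    for (k in 1:50) {
      ev <- adiabatic_eval(model, q, degeneracy_tol = 0)
      if (ev$gap < p$gap_tol / 10) break
      ggap <- 2 * ev$grad_diff_half
      gg2 <- sum(ggap^2)
      if (gg2 < 1e-20) break
      step <- ev$gap / gg2
      q_try <- q - step * ggap
      ev_try <- adiabatic_eval(model, q_try, degeneracy_tol = 0)
      halvings <- 0L
      while (ev_try$gap >= ev$gap && halvings < 30L) {
        step <- step / 2
        q_try <- q - step * ggap
        ev_try <- adiabatic_eval(model, q_try, degeneracy_tol = 0)
        halvings <- halvings + 1L
      }
      if (ev_try$gap >= ev$gap) break
      q <- q_try
    }
    q
  }

  slide_dir <- function(ev) {
    ## mean gradient projected orthogonal to the branching plane;
    ## adiabatic_eval already switches to the degenerate-pair vectors
    ## below gap 1e-8 Ha, so the plane is well defined through the seam
    B <- cbind(ev$grad_diff_half, ev$coupling_grad)
    keep <- sqrt(colSums(B^2)) > 1e-14
    g <- ev$grad_mean
    if (any(keep)) {
      Bq <- qr(B[, keep, drop = FALSE])
      g <- g - qr.fitted(Bq, g)
    }
    -g
  }

  ev <- adiabatic_eval(model, q)
  step_len <- 0.5
  while (iter < p$max_iter) {
    iter <- iter + 1L
    q_new <- restore(q)
    ev <- adiabatic_eval(model, q_new)
    d <- slide_dir(ev)
    dn <- sqrt(sum(d^2))
    moved <- sqrt(sum((q_new - q)^2))
    if (dn > 1e-12) {
      t <- step_len
      accepted <- FALSE
      while (t > 1e-15) {
        q_try <- restore(q_new + t * d / dn)
        ev_try <- adiabatic_eval(model, q_try)
        if (ev_try$mean_energy < ev$mean_energy) {
          accepted <- TRUE
          break
        }
        t <- t / 2
      }
      if (accepted) {
        moved <- moved + sqrt(sum((q_try - q_new)^2))
        q_new <- q_try
        ev <- ev_try
        step_len <- min(2 * t, 1)
      }
    }
    step_norm <- sqrt(sum((q_new - q)^2))
    q <- q_new
    trace[[iter]] <- c(ev$gap, ev$mean_energy, step_norm)
    ## contract: degenerate within tolerance and stationary (no slide step
    ## of any length decreases the seam energy further)
    if (ev$gap < p$gap_tol && step_norm < p$step_tol) {
      converged <- TRUE
      break
    }
  }
  new_optres(q, ev$gap, ev$mean_energy, iter, converged, trace)
}
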