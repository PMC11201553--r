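#' Convergence criteria for geometry optimization
#'
#' The four thresholds used to declare an optimization converged, quoted
#' in atomic units: maximum and RMS per-atom force (Hartree/Bohr) and
#' maximum and RMS per-atom displacement of the last accepted step (Bohr).
#' The defaults are the standard quantum-chemistry optimizer thresholds
#' (as used by Gaussian 16). All four must hold simultaneously, compared
#' with `<=`.
#'
#' @param max_force maximum per-atom force, Hartree/Bohr.
#' @param rms_force RMS per-atom force, Hartree/Bohr.
#' @param max_displacement maximum per-atom displacement, Bohr.
#' @param rms_displacement RMS per-atom displacement, Bohr.
#' @return an object of class `convergence_criteria`.
#' @export
convergence_criteria <- function(max_force = 0.00045,
                                 rms_force = 0.0003,
                                 max_displacement = 0.0018,
                                 rms_displacement = 0.0012) {
  vals <- c(max_force = max_force, rms_force = rms_force,
            max_displacement = max_displacement,
            rms_displacement = rms_displacement)
  if (any(vals <= 0)) stop("all convergence thresholds must be positive")
  structure(as.list(vals), class = "convergence_criteria")
}

#' Optimizer control parameters
#'
#' Tunables of the CG-BS loop. The line search is Armijo backtracking
#' (sufficient decrease with constant `armijo_c1`, step shrink factor
#' `backtrack_factor`); the curvature (second Wolfe) condition with
#' constant `curvature_c2` is evaluated and recorded per step for
#' diagnostics but not enforced. The first trial step of an iteration is
#' scaled so that the largest single-atom displacement is `initial_step`
#' Angstrom; later iterations try twice the last accepted step, capped at
#' that scale.
#'
#' @param armijo_c1 sufficient-decrease constant, 0 < c1 < 1.
#' @param curvature_c2 curvature constant, c1 < c2 < 1 (diagnostic only).
#' @param backtrack_factor multiplicative step shrink per rejected trial,
#'   in (0, 1).
#' @param initial_step largest single-atom trial displacement, Angstrom.
#' @param max_line_search_trials trials before the line search gives up.
#' @param restart_interval iterations between forced steepest-descent
#'   restarts; `NULL` (default) means the number of free coordinates
#'   (3 x free atoms).
#' @param max_iterations iteration cap; hitting it returns
#'   `converged = FALSE` rather than an error.
#' @return an object of class `cgbs_control`.
#' @export
cgbs_control <- function(armijo_c1 = 1e-4, curvature_c2 = 0.9,
                         backtrack_factor = 0.5, initial_step = 0.05,
                         max_line_search_trials = 20L,
                         restart_interval = NULL,
                         max_iterations = 5000L) {
  stopifnot(armijo_c1 > 0, armijo_c1 < curvature_c2, curvature_c2 < 1,
            backtrack_factor > 0, backtrack_factor < 1,
            initial_step > 0, max_line_search_trials >= 1,
            max_iterations >= 1)
  structure(list(armijo_c1 = armijo_c1, curvature_c2 = curvature_c2,
                 backtrack_factor = backtrack_factor,
                 initial_step = initial_step,
                 max_line_search_trials = as.integer(max_line_search_trials),
                 restart_interval = restart_interval,
                 max_iterations = as.integer(max_iterations)),
            class = "cgbs_control")
}

#' Check the four convergence criteria
#'
#' Converts free-atom forces (kcal/mol/A) and last-step displacements
#' (Angstrom) to atomic units and compares the per-atom vector norms --
#' maximum and RMS -- against the thresholds with `<=`. On the first
#' iteration there is no prior geometry, so `displacement = NULL` leaves
#' both displacement criteria unsatisfied.
#'
#' @param forces m x 3 matrix of forces on the free atoms, kcal/mol/A.
#' @param displacement m x 3 matrix of free-atom displacements for the
#'   last accepted step, Angstrom, or NULL.
#' @param criteria a [convergence_criteria()].
#' @return named logical vector
#'   `(max_force, rms_force, max_displacement, rms_displacement)`.
#' @export
check_convergence <- function(forces, displacement,
                              criteria = convergence_criteria()) {
  forces <- as_coords_matrix(forces)
  if (nrow(forces) == 0) stop("empty free-atom set")
  fnorm <- sqrt(rowSums(force_kcalmol_per_A_to_au(forces)^2))
  out <- c(max_force = max(fnorm) <= criteria$max_force,
           rms_force = sqrt(mean(fnorm^2)) <= criteria$rms_force,
           max_displacement = FALSE, rms_displacement = FALSE)
  if (!is.null(displacement)) {
    dnorm <- sqrt(rowSums(angstrom_to_bohr(
      as_coords_matrix(displacement))^2))
    out["max_displacement"] <- max(dnorm) <= criteria$max_displacement
    out["rms_displacement"] <- sqrt(mean(dnorm^2)) <=
      criteria$rms_displacement
  }
  out
}

#' Armijo backtracking line search
#'
#' Starting from trial step `alpha0`, shrinks the step by
#' `backtrack_factor` until the sufficient-decrease (Armijo) condition
#' `E(x + a d) <= E0 + c1 a (g0.d)` holds. The curvature condition
#' `g(x+ad).d >= c2 (g0.d)` is evaluated at the accepted point and
#' reported for diagnostics only. `direction` must be a descent direction
#' (`g0.d < 0`); an ascent direction is a precondition violation and an
#' error (the optimizer restarts with steepest descent before calling).
#'
#' @param model an [energy_model()].
#' @param coords current N x 3 coordinates, Angstrom.
#' @param direction N x 3 search direction (zero rows for frozen atoms).
#' @param g0 current N x 3 gradient (= -forces), kcal/mol/A.
#' @param E0 current energy, kcal/mol.
#' @param control a [cgbs_control()].
#' @param alpha0 initial trial step; default scales `direction` so the
#'   largest atomic displacement is `control$initial_step`.
#' @return on success, `list(step, coords, energy, forces, n_trials,
#'   curvature_ok, failed = FALSE)`; if Armijo is never met within
#'   `max_line_search_trials`, `list(failed = TRUE, n_trials)`.
#' @export
backtracking_search <- function(model, coords, direction, g0, E0, control,
                                alpha0 = NULL) {
  gd <- sum(g0 * direction)
  if (gd >= 0)
    stop("line search requires a descent direction (g0.d < 0); got g0.d = ",
         format(gd))
  dmax <- sqrt(max(rowSums(direction^2)))
  if (is.null(alpha0)) alpha0 <- control$initial_step / dmax
  alpha <- alpha0
  for (trial in seq_len(control$max_line_search_trials)) {
    cand <- coords + alpha * direction
    ev <- model$eval(cand)
    if (is.finite(ev$energy) &&
        ev$energy <= E0 + control$armijo_c1 * alpha * gd) {
      curv_ok <- sum(-ev$forces * direction) >= control$curvature_c2 * gd
      return(list(step = alpha, coords = cand, energy = ev$energy,
                  forces = ev$forces, n_trials = trial,
                  curvature_ok = curv_ok, failed = FALSE))
    }
    alpha <- alpha * control$backtrack_factor
  }
  list(failed = TRUE, n_trials = control$max_line_search_trials)
}

#' Conjugate-gradient minimization with backtracking line search (CG-BS)
#'
#' Minimizes the potential energy of a structure under an arbitrary
#' [energy_model()]. Directions follow nonlinear conjugate gradients with
#' the Polak-Ribiere+ update `beta = max(0, g1.(g1 - g0) / |g0|^2)`,
#' periodic steepest-descent restarts and a restart whenever the proposed
#' direction is not a descent direction; step lengths come from
#' [backtracking_search()]. Atoms flagged in `frozen_mask` never move
#' (their coordinates are bit-identical on output); convergence is
#' declared when all four criteria of [check_convergence()] hold on the
#' free atoms. A line-search failure triggers one steepest-descent restart
#' with a reduced trial step; two consecutive failures terminate with
#' `converged = FALSE`, as does reaching `max_iterations`.
#'
#' @param model an [energy_model()].
#' @param start starting geometry: a `structure3d` or an N x 3 coordinate
#'   matrix (Angstrom).
#' @param frozen_mask logical per-atom vector (TRUE = frozen), or NULL.
#' @param criteria a [convergence_criteria()].
#' @param control a [cgbs_control()].
#' @return an object of class `cgbs_fit` with components `final_coords`,
#'   `final_energy`, `n_iterations`, `converged`, `criteria_status`,
#'   `energy_trace`, a per-iteration `trace` data frame (atomic-unit force
#'   and displacement norms, step length, curvature diagnostic) and, when
#'   `start` was a `structure3d`, the optimized `structure`.
#' @examples
#' fit <- cgbs_minimize(harmonic_well_model(k = 1), rbind(c(1, 1, 1)))
#' fit$converged
#' max(abs(fit$final_coords))
#' @export
cgbs_minimize <- function(model, start, frozen_mask = NULL,
                          criteria = convergence_criteria(),
                          control = cgbs_control()) {
  stopifnot(inherits(model, "energy_model"),
            inherits(criteria, "convergence_criteria"),
            inherits(control, "cgbs_control"))
  s <- NULL
  if (inherits(start, "structure3d")) {
    s <- start
    check_model_elements(model, s)
    coords <- get_coords(s)
  } else {
    coords <- as_coords_matrix(start)
  }
  n <- nrow(coords)
  if (is.null(frozen_mask)) frozen_mask <- rep(FALSE, n)
  if (length(frozen_mask) != n)
    stop("frozen mask length (", length(frozen_mask),
         ") does not match atom count (", n, ")")
  free <- !frozen_mask
  if (!any(free)) stop("no free atoms: nothing to optimize")
  restart_interval <- control$restart_interval
  if (is.null(restart_interval)) restart_interval <- 3L * sum(free)

  x <- coords
  ev <- model$eval(x)
  if (!is.finite(ev$energy)) stop("non-finite energy at the start geometry")
  E <- ev$energy
  forces <- ev$forces
  forces[frozen_mask, ] <- 0
  g <- -forces
  d <- -g
  energy_trace <- E
  trace <- list(trace_row(0L, E, forces[free, , drop = FALSE], NULL, NA, NA))
  crit <- check_convergence(forces[free, , drop = FALSE], NULL, criteria)
  converged <- FALSE
  alpha_prev <- NULL
  since_restart <- 0L
  k <- 0L

  while (k < control$max_iterations) {
    gd <- sum(g * d)
    if (gd >= 0) {                      # not a descent direction: restart
      d <- -g
      since_restart <- 0L
      gd <- sum(g * d)
      if (gd >= -1e-300) {              # gradient is (numerically) zero
        crit <- check_convergence(forces[free, , drop = FALSE],
                                  matrix(0, sum(free), 3), criteria)
        converged <- all(crit)
        break
      }
    }
    dmax <- sqrt(max(rowSums(d^2)))
    alpha_cap <- control$initial_step / dmax
    alpha0 <- if (is.null(alpha_prev)) alpha_cap else
      min(2 * alpha_prev, alpha_cap)
    ls <- backtracking_search(model, x, d, g, E, control, alpha0)
    if (ls$failed) {                    # retry once from steepest descent
      d <- -g
      since_restart <- 0L
      ls <- backtracking_search(model, x, d, g, E, control,
                                0.1 * control$initial_step /
                                  sqrt(max(rowSums(d^2))))
      if (ls$failed) break              # two consecutive failures
    }
    k <- k + 1L
    disp <- ls$coords - x
    x <- ls$coords
    new_forces <- ls$forces
    new_forces[frozen_mask, ] <- 0
    g_new <- -new_forces
    E <- ls$energy
    energy_trace <- c(energy_trace, E)
    crit <- check_convergence(new_forces[free, , drop = FALSE],
                              disp[free, , drop = FALSE], criteria)
    trace[[length(trace) + 1L]] <-
      trace_row(k, E, new_forces[free, , drop = FALSE],
                disp[free, , drop = FALSE], ls$step, ls$curvature_ok)
    if (all(crit)) {
      converged <- TRUE
      forces <- new_forces
      break
    }
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    since_restart <- since_restart + 1L
    if (since_restart >= restart_interval) {
      beta <- 0
      since_restart <- 0L
    }
    d <- -g_new + beta * d
    g <- g_new
    forces <- new_forces
    alpha_prev <- ls$step
  }

  out <- list(final_coords = x, final_energy = E, n_iterations = k,
              converged = converged, criteria_status = crit,
              energy_trace = energy_trace,
              trace = do.call(rbind, trace),
              criteria = criteria, control = control,
              model_label = model$label, frozen_mask = frozen_mask)
  if (!is.null(s)) out$structure <- set_coords(s, x)
  class(out) <- "cgbs_fit"
  out
}

trace_row <- function(iter, energy, f_free, d_free, step, curvature_ok) {
  fn <- sqrt(rowSums(force_kcalmol_per_A_to_au(f_free)^2))
  if (is.null(d_free)) {
    dmax <- NA_real_; drms <- NA_real_
  } else {
    dn <- sqrt(rowSums(angstrom_to_bohr(d_free)^2))
    dmax <- max(dn); drms <- sqrt(mean(dn^2))
  }
  data.frame(iter = iter, energy = energy,
             max_force_au = max(fn), rms_force_au = sqrt(mean(fn^2)),
             max_disp_au = dmax, rms_disp_au = drms,
             step = step, curvature_ok = curvature_ok)
}

#' @export
print.cgbs_fit <- function(x, ...) {
  cat(sprintf("CG-BS minimization (%s): %s after %d iteration(s)\n",
              x$model_label,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  final energy: %.6f kcal/mol\n", x$final_energy))
  invisible(x)
}

#' @export
summary.cgbs_fit <- function(object, ...) {
  x <- object
  print(x)
  st <- x$criteria_status
  th <- unlist(x$criteria)
  last <- x$trace[nrow(x$trace), ]
  vals <- c(last$max_force_au, last$rms_force_au,
            last$max_disp_au, last$rms_disp_au)
  cat("  convergence criteria (atomic units):\n")
  for (i in seq_along(st))
    cat(sprintf("    %-17s %12.6f  (<= %7.5f)  %s\n", names(st)[i],
                vals[i], th[i], if (st[i]) "YES" else "NO"))
  cat(sprintf("  frozen atoms: %d of %d\n", sum(x$frozen_mask),
              length(x$frozen_mask)))
  invisible(x)
}

#' @export
coef.cgbs_fit <- function(object, ...) object$final_coords

#' @export
plot.cgbs_fit <- function(x, ...) {
  plot(seq_along(x$energy_trace) - 1L, x$energy_trace, type = "b",
       xlab = "iteration", ylab = "energy (kcal/mol)",
       main = sprintf("CG-BS energy trace (%s)", x$model_label), ...)
  invisible(x)
}
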