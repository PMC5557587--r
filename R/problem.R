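#' Default parameter bounds
#'
#' States are normalized to [0,1], so the defaults span Hill shapes from
#' near-linear (n = 1) to switch-like (n = 10), half-saturations across the
#' state range, and life-times over two decades.
#'
#' @return list with elements \code{n}, \code{k}, \code{tau}, \code{x0},
#'   each \code{c(lower, upper)}
#' @export
default_bounds <- function() {
  list(n = c(1, 10), k = c(0.01, 1), tau = c(0.1, 10), x0 = c(0, 1))
}

#' Define the mixed-integer fitting problem
#'
#' Lays out the flat decision vector for a hypergraph + dataset pair: the
#' continuous block holds one (n, k) pair per hyperedge-input occurrence, one
#' tau per non-input state, the estimated initial conditions, and any
#' piecewise-constant control levels; the integer block holds one binary
#' selector w per hyperedge (plus integer control levels).  The encoding is
#' a deterministic bijection: names are stable across runs.
#'
#' @param hypergraph from \code{\link{expand_prior_network}}
#' @param experiments list of \code{\link{experiment}} objects carrying
#'   measurements
#' @param bounds as \code{\link{default_bounds}} (partial overrides allowed)
#' @param estimate_x0 species whose initial condition is estimated (shared
#'   across experiments)
#' @param normalized use normalized Hill transforms
#' @param cvp optional control parameterization from
#'   \code{\link{control_parameterization}}
#' @param penalty objective value returned on integrator failure
#' @return object of class \code{fit_problem}
#' @export
fit_problem <- function(hypergraph, experiments, bounds = list(),
                        estimate_x0 = character(0), normalized = TRUE,
                        cvp = NULL, penalty = 1e10) {
  stopifnot(inherits(hypergraph, "hypergraph"))
  if (inherits(experiments, "lg_experiment")) experiments <- list(experiments)
  b <- utils::modifyList(default_bounds(), bounds)
  sp <- hypergraph$species
  bad <- setdiff(estimate_x0, sp)
  if (length(bad)) stop("estimate_x0 species not in model: ",
                        paste(bad, collapse = ", "))
  cont_names <- character(0); cont_lb <- numeric(0); cont_ub <- numeric(0)
  for (e in hypergraph$hyperedges) {
    for (s in e$inputs$species) {
      cont_names <- c(cont_names, sprintf("n|e%d|%s", e$id, s),
                      sprintf("k|e%d|%s", e$id, s))
      cont_lb <- c(cont_lb, b$n[1], b$k[1])
      cont_ub <- c(cont_ub, b$n[2], b$k[2])
    }
  }
  dyn_sp <- setdiff(sp, hypergraph$input_species)
  cont_names <- c(cont_names, sprintf("tau|%s", dyn_sp))
  cont_lb <- c(cont_lb, rep(b$tau[1], length(dyn_sp)))
  cont_ub <- c(cont_ub, rep(b$tau[2], length(dyn_sp)))
  if (length(estimate_x0)) {
    cont_names <- c(cont_names, sprintf("x0|%s", estimate_x0))
    cont_lb <- c(cont_lb, rep(b$x0[1], length(estimate_x0)))
    cont_ub <- c(cont_ub, rep(b$x0[2], length(estimate_x0)))
  }
  int_names <- sprintf("w|e%d", seq_along(hypergraph$hyperedges))
  int_lb <- rep(0, length(int_names)); int_ub <- rep(1, length(int_names))
  if (!is.null(cvp)) {
    stopifnot(inherits(cvp, "control_parameterization"))
    rho <- length(cvp$mesh) - 1L
    for (j in seq_along(cvp$controls)) {
      nm <- sprintf("%s|%s|el%d",
                    if (cvp$integer[j]) "wi" else "wu", cvp$controls[j],
                    seq_len(rho))
      if (cvp$integer[j]) {
        int_names <- c(int_names, nm)
        int_lb <- c(int_lb, rep(cvp$lb[j], rho))
        int_ub <- c(int_ub, rep(cvp$ub[j], rho))
      } else {
        cont_names <- c(cont_names, nm)
        cont_lb <- c(cont_lb, rep(cvp$lb[j], rho))
        cont_ub <- c(cont_ub, rep(cvp$ub[j], rho))
      }
    }
  }
  n_data <- sum(vapply(experiments, function(e) sum(!is.na(e$ybar)), 0))
  if (n_data <= 0) stop("no non-missing measurements in the experiments")
  structure(list(hypergraph = hypergraph, experiments = experiments,
                 bounds = b, estimate_x0 = estimate_x0,
                 normalized = normalized, cvp = cvp, penalty = penalty,
                 cont_names = cont_names, int_names = int_names,
                 lb = c(cont_lb, int_lb), ub = c(cont_ub, int_ub),
                 n_cont = length(cont_names),
                 int_mask = c(rep(FALSE, length(cont_names)),
                              rep(TRUE, length(int_names))),
                 n_data = n_data),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat("Mixed-integer logic-ODE fitting problem\n")
  cat("  decision vector: ", x$n_cont, " continuous + ",
      length(x$int_names), " integer\n", sep = "")
  cat("  experiments:     ", length(x$experiments), " (",
      x$n_data, " measurements)\n", sep = "")
  invisible(x)
}

#' Encode model parameters into a flat decision vector (and back)
#'
#' \code{decode_decision(encode_decision(p))} is the identity; ordering is
#' deterministic (hyperedge id, then input order; tau in species order).
#'
#' @param params list with elements \code{gate_params} (list of n,k matrices
#'   per hyperedge), \code{tau} (named, non-input species), \code{w}
#'   (selector vector), optional \code{x0} (named, estimated entries),
#'   optional \code{cvp_levels}
#' @param problem a \code{fit_problem}
#' @return named numeric vector (continuous block then integer block)
#' @export
encode_decision <- function(params, problem) {
  x <- stats::setNames(numeric(length(problem$lb)),
                       c(problem$cont_names, problem$int_names))
  for (e in problem$hypergraph$hyperedges) {
    gp <- as.matrix(params$gate_params[[e$id]])
    for (j in seq_len(nrow(gp))) {
      s <- e$inputs$species[j]
      x[sprintf("n|e%d|%s", e$id, s)] <- gp[j, 1L]
      x[sprintf("k|e%d|%s", e$id, s)] <- gp[j, 2L]
    }
  }
  dyn_sp <- setdiff(problem$hypergraph$species,
                    problem$hypergraph$input_species)
  x[sprintf("tau|%s", dyn_sp)] <- params$tau[dyn_sp]
  if (length(problem$estimate_x0))
    x[sprintf("x0|%s", problem$estimate_x0)] <- params$x0[problem$estimate_x0]
  x[sprintf("w|e%d", seq_along(params$w))] <- params$w
  if (!is.null(params$cvp_levels))
    x[names(params$cvp_levels)] <- params$cvp_levels
  bad <- x < problem$lb - 1e-12 | x > problem$ub + 1e-12
  if (any(bad)) stop("encoded values out of bounds: ",
                     paste(names(x)[bad], collapse = ", "))
  x
}

#' @rdname encode_decision
#' @param x flat decision vector
#' @export
decode_decision <- function(x, problem) {
  if (length(x) != length(problem$lb))
    stop("decision vector has length ", length(x), ", expected ",
         length(problem$lb))
  names(x) <- c(problem$cont_names, problem$int_names)
  gate_params <- vector("list", length(problem$hypergraph$hyperedges))
  for (e in problem$hypergraph$hyperedges) {
    s <- e$inputs$species
    gate_params[[e$id]] <- cbind(
      n = unname(x[sprintf("n|e%d|%s", e$id, s)]),
      k = unname(x[sprintf("k|e%d|%s", e$id, s)]))
  }
  dyn_sp <- setdiff(problem$hypergraph$species,
                    problem$hypergraph$input_species)
  tau <- stats::setNames(unname(x[sprintf("tau|%s", dyn_sp)]), dyn_sp)
  x0 <- NULL
  if (length(problem$estimate_x0))
    x0 <- stats::setNames(unname(x[sprintf("x0|%s", problem$estimate_x0)]),
                          problem$estimate_x0)
  w <- unname(x[sprintf("w|e%d", seq_along(gate_params))])
  cvp_levels <- NULL
  if (!is.null(problem$cvp)) {
    nm <- grep("^w[ui]\\|", names(x), value = TRUE)
    cvp_levels <- x[nm]
  }
  list(gate_params = gate_params, tau = tau, w = w, x0 = x0,
       cvp_levels = cvp_levels)
}

# builds the full model for a decoded decision
.decision_model <- function(dec, problem) {
  sp <- problem$hypergraph$species
  tau <- stats::setNames(rep(1, length(sp)), sp)
  tau[names(dec$tau)] <- dec$tau
  x0 <- stats::setNames(rep(0, length(sp)), sp)
  if (!is.null(dec$x0)) x0[names(dec$x0)] <- dec$x0
  logic_ode_model(problem$hypergraph, tau = tau,
                  gate_params = dec$gate_params, w = dec$w, x0 = x0,
                  normalized = problem$normalized)
}

#' Least-squares objective over all experiments
#'
#' Decodes the decision vector, keeps the sub-hypergraph selected by w,
#' simulates every experiment and returns the sum of squared residuals over
#' experiments, observables and sampling points, skipping missing
#' measurements.  Integrator failure yields the finite penalty value
#' (\code{problem$penalty + number of failed experiments}) so that solvers
#' can still rank failures.
#'
#' @param x flat decision vector (integer entries must be integral)
#' @param problem a \code{fit_problem}
#' @param rtol,atol integration tolerances
#' @return scalar F >= 0
#' @export
objective <- function(x, problem, rtol = 1e-6, atol = 1e-8) {
  dec <- decode_decision(x, problem)
  model <- .decision_model(dec, problem)
  ssr <- 0; failed <- 0L
  for (ex in problem$experiments) {
    tr <- if (is.null(problem$cvp))
      simulate_model(model, ex, rtol = rtol, atol = atol)
    else
      .simulate_piecewise(model, ex, problem$cvp, dec$cvp_levels,
                          rtol = rtol, atol = atol)
    if (tr$status != "success") { failed <- failed + 1L; next }
    if (is.null(ex$ybar) || !length(ex$observed)) next
    yhat <- tr$states[, ex$observed, drop = FALSE]
    r <- ex$ybar - yhat
    ssr <- ssr + sum(r^2, na.rm = TRUE)
  }
  if (failed > 0L) return(problem$penalty + failed)
  ssr
}

#' Akaike information criterion for model comparison
#'
#' \code{aic} uses the criterion in the form \eqn{2K + 2 n \ln(F/n)} (with
#' the number of data points n inside the logarithm); \code{standard_aic}
#' provides the common \eqn{n \ln(F/n) + 2K} variant.
#'
#' @param K number of active parameters (see
#'   \code{\link{count_active_params}})
#' @param n number of (non-missing) data points
#' @param F least-squares objective value, F > 0
#' @return AIC value; F = 0 returns -Inf with a warning (log singularity)
#' @export
aic <- function(K, n, F) {
  stopifnot(K >= 0, n > 0, F >= 0)
  if (F == 0) {
    warning("F = 0: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  2 * K + 2 * n * log(F / n)
}

#' @rdname aic
#' @export
standard_aic <- function(K, n, F) {
  stopifnot(K >= 0, n > 0, F >= 0)
  if (F == 0) {
    warning("F = 0: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  n * log(F / n) + 2 * K
}

#' Count active parameters of a decision
#'
#' K = 2 x (inputs of selected hyperedges: one n and one k each) + (tau of
#' states with at least one selected incoming hyperedge) + (estimated
#' initial conditions) + (selected selectors w = 1).
#'
#' @param x flat decision vector
#' @param problem a \code{fit_problem}
#' @return integer K
#' @export
count_active_params <- function(x, problem) {
  dec <- decode_decision(x, problem)
  sel <- which(dec$w == 1)
  n_inputs <- sum(vapply(problem$hypergraph$hyperedges[sel],
                         function(e) nrow(e$inputs), 1L))
  tgts <- unique(vapply(problem$hypergraph$hyperedges[sel],
                        function(e) e$target, ""))
  2L * n_inputs + length(tgts) + length(problem$estimate_x0) + length(sel)
}

#' Coordinate-dependence mask of the objective
#'
#' Returns a function mapping a decision vector to the logical mask of
#' coordinates the objective actually depends on there: (n, k) of selected
#' hyperedges, tau of states with a selected incoming gate, estimated
#' initial conditions, control levels and every selector.  The objective is
#' exactly invariant to the remaining (inactive) coordinates, so local
#' descent can skip their finite-difference columns.
#'
#' @param problem a \code{fit_problem}
#' @return function(x) -> logical vector
#' @export
active_coords_fn <- function(problem) {
  hg <- problem$hypergraph
  n_all <- length(problem$lb)
  nm <- c(problem$cont_names, problem$int_names)
  # per-hyperedge: which coordinate indices belong to it
  edge_coords <- lapply(hg$hyperedges, function(e)
    which(grepl(sprintf("^[nk]\\|e%d\\|", e$id), nm)))
  tau_idx <- stats::setNames(
    match(sprintf("tau|%s", setdiff(hg$species, hg$input_species)), nm),
    setdiff(hg$species, hg$input_species))
  w_idx <- match(sprintf("w|e%d", seq_along(hg$hyperedges)), nm)
  targets <- vapply(hg$hyperedges, function(e) e$target, "")
  always <- grepl("^(x0|wu|wi)\\|", nm)
  function(x) {
    act <- always
    act[w_idx] <- TRUE
    sel <- which(x[w_idx] == 1)
    for (e in sel) act[edge_coords[[e]]] <- TRUE
    act[tau_idx[unique(targets[sel])]] <- TRUE
    act
  }
}

# ---- control vector parameterization ------------------------------------

#' Piecewise-constant control parameterization
#'
#' Discretizes time-dependent controls (stimulus schedules) into rho
#' piecewise-constant elements over [t0, tf]; each element level becomes a
#' static decision variable (continuous w_u, or integer w_i when flagged).
#'
#' @param mesh increasing breakpoints t0 = mesh[1] < ... < mesh[rho+1] = tf
#' @param controls character vector of controlled (input) species
#' @param integer logical per control: restrict levels to integers
#' @param lb,ub level bounds per control (default [0,1])
#' @return object of class \code{control_parameterization}
#' @export
control_parameterization <- function(mesh, controls, integer = FALSE,
                                     lb = 0, ub = 1) {
  mesh <- as.numeric(mesh)
  if (length(mesh) < 2L || is.unsorted(mesh, strictly = TRUE))
    stop("mesh must be at least 2 strictly increasing breakpoints")
  k <- length(controls)
  structure(list(mesh = mesh, controls = as.character(controls),
                 integer = rep_len(as.logical(integer), k),
                 lb = rep_len(lb, k), ub = rep_len(ub, k)),
            class = "control_parameterization")
}

#' Materialize control functions from their levels
#'
#' @param cvp a \code{\link{control_parameterization}}
#' @param levels matrix (rho x n_controls) or vector of per-element levels
#' @return named list of step functions u(t) (right-open elements; the last
#'   element includes tf)
#' @export
parameterize_controls <- function(cvp, levels) {
  stopifnot(inherits(cvp, "control_parameterization"))
  rho <- length(cvp$mesh) - 1L
  if (length(levels) != rho * length(cvp$controls))
    stop("need ", rho, " levels for each of ", length(cvp$controls),
         " controls")
  levels <- matrix(levels, nrow = rho)
  if (ncol(levels) != length(cvp$controls))
    stop("need ", rho, " levels for each of ", length(cvp$controls),
         " controls")
  for (j in seq_along(cvp$controls)) {
    if (cvp$integer[j] && any(levels[, j] != round(levels[, j])))
      stop("integer control '", cvp$controls[j],
           "' has non-integral level(s)")
    if (any(levels[, j] < cvp$lb[j] - 1e-12 | levels[, j] > cvp$ub[j] + 1e-12))
      stop("levels of control '", cvp$controls[j], "' outside bounds")
  }
  out <- lapply(seq_along(cvp$controls), function(j) {
    lev <- levels[, j]; mesh <- cvp$mesh
    function(t) {
      i <- findInterval(t, mesh, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), rho)
      lev[i]
    }
  })
  stats::setNames(out, cvp$controls)
}

# extract the level matrix for a control from the flat cvp_levels block
.cvp_level_matrix <- function(cvp, cvp_levels) {
  rho <- length(cvp$mesh) - 1L
  sapply(seq_along(cvp$controls), function(j) {
    pre <- if (cvp$integer[j]) "wi" else "wu"
    unname(cvp_levels[sprintf("%s|%s|el%d", pre, cvp$controls[j],
                              seq_len(rho))])
  })
}

# piecewise integration: restart at each mesh element with the element's
# clamp levels for the controlled species
.simulate_piecewise <- function(model, ex, cvp, cvp_levels, rtol, atol) {
  lev <- .cvp_level_matrix(cvp, cvp_levels)
  rho <- length(cvp$mesh) - 1L
  model <- apply_perturbations(model, ex)
  x0 <- model$x0
  all_states <- NULL; all_times <- numeric(0)
  for (el in seq_len(rho)) {
    t0 <- cvp$mesh[el]; t1 <- cvp$mesh[el + 1L]
    stim <- ex$stimuli
    stim[cvp$controls] <- lev[el, ]
    seg_times <- ex$times[ex$times >= t0 & (ex$times < t1 | el == rho)]
    ex_el <- experiment(stimuli = stim, inhibitors = ex$inhibitors,
                        observed = ex$observed,
                        times = sort(unique(c(t0, seg_times, t1))) - t0,
                        id = ex$id)
    m_el <- model; m_el$x0 <- x0
    tr <- simulate_model(m_el, ex_el, rtol = rtol, atol = atol)
    if (tr$status != "success")
      return(structure(list(times = ex$times,
                            states = matrix(NA_real_, length(ex$times),
                                            length(x0)),
                            status = "failure", experiment = ex$id),
                       class = "trajectory"))
    x0 <- tr$states[nrow(tr$states), ]
    keep <- (tr$times + t0) %in% seg_times
    all_states <- rbind(all_states, tr$states[keep, , drop = FALSE])
    all_times <- c(all_times, tr$times[keep] + t0)
  }
  ord <- order(all_times)
  keep <- !duplicated(all_times[ord])
  structure(list(times = all_times[ord][keep],
                 states = all_states[ord, , drop = FALSE][keep, , drop = FALSE],
                 status = "success", experiment = ex$id),
            class = "trajectory")
}
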