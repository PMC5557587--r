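#' Logic-based ODE model
#'
#' Couples an expanded hypergraph with its continuous parameters into the
#' dynamic system \deqn{\dot{\bar x}_i = (\bar B_i(\bar x) - \bar x_i) /
#' \tau_i,} where \eqn{\bar B_i} is the continuous OR over the state's
#' selected (w = 1) AND gates, each gate the product of its (normalized)
#' Hill-transformed, sign-adjusted inputs, and \eqn{\tau_i} acts as the
#' life-time of state i.  Input species (no incoming hyperedges) have zero
#' derivative and are held at their experimental stimulus level; a state
#' whose every candidate gate is deselected decays exponentially to 0.
#'
#' @param hypergraph an object from \code{\link{expand_prior_network}}
#' @param tau named vector of life-times (> 0), one per species (entries for
#'   input species are ignored); a single unnamed value is recycled
#' @param gate_params list, one matrix per hyperedge, with columns
#'   \code{n}, \code{k} and one row per gate input
#' @param w binary selector vector, one entry per hyperedge
#' @param x0 named initial-state vector in [0,1]; defaults to 0
#' @param normalized use normalized Hill transforms (default \code{TRUE})
#' @return object of class \code{logic_ode_model}
#' @export
logic_ode_model <- function(hypergraph, tau, gate_params, w,
                            x0 = NULL, normalized = TRUE) {
  stopifnot(inherits(hypergraph, "hypergraph"))
  sp <- hypergraph$species
  nE <- length(hypergraph$hyperedges)
  if (length(tau) == 1L && is.null(names(tau)))
    tau <- stats::setNames(rep(tau, length(sp)), sp)
  if (!all(sp %in% names(tau))) stop("tau must name every species")
  tau <- tau[sp]
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("all tau must be > 0")
  if (length(w) != nE) stop("w must have one entry per hyperedge (", nE, ")")
  if (!all(w %in% c(0, 1))) stop("w entries must be 0 or 1")
  if (length(gate_params) != nE)
    stop("gate_params must have one element per hyperedge")
  for (i in seq_len(nE)) {
    gp <- as.matrix(gate_params[[i]])
    if (nrow(gp) != nrow(hypergraph$hyperedges[[i]]$inputs))
      stop("gate_params[[", i, "]] needs one (n,k) row per input")
    if (any(gp <= 0)) stop("Hill parameters must be > 0 (hyperedge ", i, ")")
    gate_params[[i]] <- gp
  }
  if (is.null(x0)) x0 <- stats::setNames(rep(0, length(sp)), sp)
  x0full <- stats::setNames(rep(0, length(sp)), sp)
  x0full[names(x0)] <- x0
  if (any(x0full < 0 | x0full > 1)) stop("x0 must lie in [0,1]")
  structure(list(hypergraph = hypergraph, tau = tau,
                 gate_params = gate_params, w = as.numeric(w),
                 x0 = x0full, normalized = isTRUE(normalized),
                 clamped = stats::setNames(numeric(0), character(0)),
                 inhibited = character(0)),
            class = "logic_ode_model")
}

#' @export
print.logic_ode_model <- function(x, ...) {
  cat("Logic-based ODE model: ", length(x$hypergraph$species), " states, ",
      sum(x$w), "/", length(x$w), " hyperedges selected\n", sep = "")
  invisible(x)
}

#' Perturbation experiments
#'
#' @param stimuli named numeric vector of clamp levels in [0,1] for
#'   stimulated species
#' @param inhibitors character vector of species whose activation is blocked
#'   (their \eqn{\bar B} is forced to 0 while the inhibitor is on)
#' @param observed character vector of measured species
#' @param times strictly increasing sampling times, \code{times[1] >= 0};
#'   measurements at t = 0 are compared against the initial state
#' @param ybar optional measurement matrix (rows = times, cols = observed;
#'   NA = missing)
#' @param id experiment identifier
#' @return object of class \code{lg_experiment}
#' @export
experiment <- function(stimuli = numeric(0), inhibitors = character(0),
                       observed = character(0), times = c(0, 10),
                       ybar = NULL, id = "exp") {
  if (length(stimuli) && is.null(names(stimuli)))
    stop("stimuli must be a named vector")
  if (any(stimuli < 0 | stimuli > 1)) stop("stimulus levels must be in [0,1]")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("times must start at or after t0 = 0")
  if (!is.null(ybar)) {
    ybar <- as.matrix(ybar)
    if (nrow(ybar) != length(times) || ncol(ybar) != length(observed))
      stop("ybar must be a length(times) x length(observed) matrix")
    colnames(ybar) <- observed
  }
  structure(list(stimuli = stimuli, inhibitors = unique(inhibitors),
                 observed = observed, times = as.numeric(times),
                 ybar = ybar, id = id),
            class = "lg_experiment")
}

#' Apply a perturbation experiment to a model
#'
#' Stimulated species are clamped at their stimulus level for all t >= 0;
#' unstimulated input species are clamped at 0; inhibited species have their
#' gate activation forced to 0 (signal blocking) while keeping the ODE
#' dimension fixed.
#'
#' @param model a \code{logic_ode_model}
#' @param exper an \code{\link{experiment}}
#' @return the perturbed model (clamp levels and inhibition recorded)
#' @export
apply_perturbations <- function(model, exper) {
  stopifnot(inherits(model, "logic_ode_model"), inherits(exper, "lg_experiment"))
  sp <- model$hypergraph$species
  unknown <- setdiff(c(names(exper$stimuli), exper$inhibitors,
                       exper$observed), sp)
  if (length(unknown))
    stop("unknown species in experiment '", exper$id, "': ",
         paste(unknown, collapse = ", "))
  clamped <- stats::setNames(rep(0, length(model$hypergraph$input_species)),
                             model$hypergraph$input_species)
  for (s in names(exper$stimuli)) clamped[s] <- exper$stimuli[s]
  model$clamped <- clamped
  model$inhibited <- exper$inhibitors
  model$x0[names(clamped)] <- clamped
  model
}

# ---- packed representation for the compiled RHS -------------------------

# Builds the flat double vector documented in src/logic_rhs.c.  The gate
# table depends only on (w, gate_params); clamp/inhibition are per
# experiment.
pack_logic_model <- function(model) {
  hg <- model$hypergraph
  sp <- hg$species
  n <- length(sp)
  idx <- stats::setNames(seq_along(sp) - 1L, sp)  # 0-based for C
  inc <- incoming_hyperedges(hg)
  gcount <- numeric(n); gstart <- numeric(n)
  table_body <- numeric(0)
  head_len <- 2L + 5L * n
  for (i in seq_len(n)) {
    eids <- inc[[sp[i]]]
    eids <- eids[model$w[eids] == 1]
    gcount[i] <- length(eids)
    gstart[i] <- head_len + length(table_body)
    for (e in eids) {
      he <- hg$hyperedges[[e]]
      gp <- model$gate_params[[e]]
      quad <- rbind(idx[he$inputs$species], he$inputs$sign, gp[, 1L], gp[, 2L])
      table_body <- c(table_body, nrow(he$inputs), as.numeric(quad))
    }
  }
  clampv <- as.numeric(sp %in% names(model$clamped))
  # input species are always clamped even without an explicit experiment
  clampv[sp %in% hg$input_species] <- 1
  inhibv <- as.numeric(sp %in% model$inhibited)
  c(n, as.numeric(model$normalized), model$tau, clampv, inhibv,
    gcount, gstart, table_body)
}

#' Build the ODE right-hand side in R
#'
#' Returns the function (t, x) -> dx/dt implementing the model dynamics.
#' This is the plain-R mirror of the compiled evaluator used by
#' \code{\link{simulate_model}}; the two paths are interchangeable.
#'
#' @param model a \code{logic_ode_model} (optionally perturbed by
#'   \code{\link{apply_perturbations}})
#' @return function of (t, x) returning the derivative vector
#' @export
build_rhs <- function(model) {
  hg <- model$hypergraph
  sp <- hg$species
  inc <- incoming_hyperedges(hg)
  clamped_sp <- union(names(model$clamped), hg$input_species)
  f <- if (model$normalized) normalized_hill else hill
  function(t, x) {
    dx <- numeric(length(sp))
    names(dx) <- sp
    for (i in seq_along(sp)) {
      s <- sp[i]
      if (s %in% clamped_sp) next  # derivative 0
      B <- 0
      if (!(s %in% model$inhibited)) {
        eids <- inc[[s]]
        eids <- eids[model$w[eids] == 1]
        if (length(eids)) {
          z <- vapply(eids, function(e) {
            he <- hg$hyperedges[[e]]
            gp <- model$gate_params[[e]]
            xi <- pmin(pmax(x[he$inputs$species], 0), 1)
            g <- f(xi, gp[, 1L], gp[, 2L])
            g <- ifelse(he$inputs$sign > 0, g, 1 - g)
            prod(g)
          }, 1.0)
          B <- 1 - prod(1 - z)
        }
      }
      dx[i] <- (B - x[i]) / model$tau[s]
    }
    dx
  }
}

#' Simulate a perturbation experiment
#'
#' Integrates the logic-based ODE with a stiff-capable variable-step solver
#' (\code{deSolve::lsoda}) and returns the states at the experiment's
#' sampling times.  Integrator failure is reported in the trajectory status,
#' never as an error.
#'
#' @param model a \code{logic_ode_model}
#' @param exper an \code{\link{experiment}}; its stimuli/inhibitors are
#'   applied before integration
#' @param rtol,atol integration tolerances
#' @param engine \code{"compiled"} (default) or \code{"r"} (pure-R RHS,
#'   mainly for cross-checking)
#' @param maxsteps integrator step budget per output interval; parameter
#'   corners that exceed it are reported as failures (the objective maps
#'   them to a finite penalty) instead of consuming unbounded time
#' @return object of class \code{trajectory}: list(times, states, status)
#' @export
simulate_model <- function(model, exper = experiment(), rtol = 1e-6,
                           atol = 1e-8, engine = c("compiled", "r"),
                           maxsteps = 2000L) {
  engine <- match.arg(engine)
  model <- apply_perturbations(model, exper)
  times <- exper$times
  tt <- unique(c(0, times))
  x0 <- model$x0
  if (length(tt) == 1L) {  # zero-length horizon
    states <- matrix(x0, nrow = length(times), ncol = length(x0),
                     byrow = TRUE, dimnames = list(NULL, names(x0)))
    return(structure(list(times = times, states = states, status = "success",
                          experiment = exper$id), class = "trajectory"))
  }
  out <- tryCatch(suppressWarnings({
    if (engine == "compiled") {
      .Call("C_set_logic_parms", pack_logic_model(model),
            PACKAGE = "logicess")
      deSolve::lsoda(y = unname(x0), times = tt, func = "C_logic_derivs",
                     parms = numeric(0), dllname = "logicess",
                     initfunc = NULL, rtol = rtol, atol = atol,
                     maxsteps = maxsteps)
    } else {
      rhs <- build_rhs(model)
      deSolve::lsoda(y = x0, times = tt,
                     func = function(t, y, p) list(unname(rhs(t, y))),
                     parms = NULL, rtol = rtol, atol = atol,
                     maxsteps = maxsteps)
    }
  }), error = function(e) NULL)
  ok <- !is.null(out) && nrow(out) == length(tt) && !anyNA(out)
  if (!ok)
    return(structure(list(times = times,
                          states = matrix(NA_real_, length(times), length(x0),
                                          dimnames = list(NULL, names(x0))),
                          status = "failure", experiment = exper$id),
                     class = "trajectory"))
  states <- out[match(times, tt), -1L, drop = FALSE]
  states <- matrix(as.numeric(states), nrow = length(times),
                   dimnames = list(NULL, names(x0)))
  structure(list(times = times, states = states, status = "success",
                 experiment = exper$id), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory (", x$status, "): ", length(x$times), " time points x ",
      ncol(x$states), " states\n", sep = "")
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a \code{trajectory}
#' @param ... unused
#' @return data.frame with columns time, species, value, experiment
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$states)),
             species = rep(colnames(x$states), each = length(x$times)),
             value = as.vector(x$states),
             experiment = x$experiment,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.trajectory
#' @param path output CSV path
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
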