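#' Fit a logic-based ODE model to perturbation data
#'
#' The main entry point: expands the signed prior network into the
#' candidate AND/OR hypergraph, encodes the mixed-integer decision vector
#' (Hill n and k per gate input, life-time tau per dynamic state, binary
#' selector w per hyperedge) and minimizes the sum of squared residuals
#' over all experiments with the cooperative enhanced scatter search.
#' With \code{criterion = "aic"} the search minimizes the Akaike
#' information criterion instead, performing structure reduction: the fit
#' then trades data mismatch against the number of active parameters.
#'
#' @param network a signed-edge data.frame (see \code{\link{signed_edges}}),
#'   a path to a SIF file, or an already-expanded \code{hypergraph}
#' @param data list of \code{\link{experiment}} objects carrying
#'   measurements, or a path to a MIDAS-like CSV
#' @param max_and_order AND-gate order cap used when expanding a network
#' @param bounds parameter-bound overrides (see
#'   \code{\link{default_bounds}})
#' @param estimate_x0 species whose initial condition is estimated
#' @param criterion \code{"sse"} (least squares) or \code{"aic"} (model
#'   reduction)
#' @param method \code{"cooperative"} (island search, default) or
#'   \code{"ess"} (single search)
#' @param n_islands islands for the cooperative method
#' @param max_evals,max_time,vtr stopping criteria (at least one required)
#' @param seed RNG seed (recorded in the result)
#' @param aic_f_floor lower floor applied to F inside the AIC (guards the
#'   log singularity of a perfect fit; see the package vignette)
#' @param species optional fixed species universe for the expansion
#' @param ... further arguments passed to \code{\link{run_cooperative}} or
#'   \code{\link{ess_run}}
#' @return an object of class \code{logic_ode_fit}
#' @examples
#' \donttest{
#' truth <- generate_network(n_species = 4, n_stimuli = 1, seed = 7)
#' bench <- generate_pseudodata(truth, noise_rel = 0, seed = 7)
#' fit <- logic_ode_fit(truth$edges, bench$experiments,
#'                      max_evals = 4000, seed = 1)
#' print(fit)
#' }
#' @export
logic_ode_fit <- function(network, data, max_and_order = 2L,
                          bounds = list(), estimate_x0 = character(0),
                          criterion = c("sse", "aic"),
                          method = c("cooperative", "ess"),
                          n_islands = 4L, max_evals = NULL,
                          max_time = NULL, vtr = NULL, seed = NULL,
                          aic_f_floor = 1e-8, species = NULL, ...) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  cl <- match.call()
  if (is.character(network)) network <- read_sif(network)
  hg <- if (inherits(network, "hypergraph")) network
        else expand_prior_network(network, max_and_order = max_and_order,
                                  species = species)
  if (is.character(data)) data <- read_midas(data)
  problem <- fit_problem(hg, data, bounds = bounds,
                         estimate_x0 = estimate_x0)
  fn <- if (criterion == "sse") {
    function(x) objective(x, problem)
  } else {
    function(x) {
      F <- objective(x, problem)
      if (F >= problem$penalty) return(F)
      aic(count_active_params(x, problem), problem$n_data,
          max(F, aic_f_floor))
    }
  }
  act <- active_coords_fn(problem)
  t0 <- proc.time()[["elapsed"]]
  res <- if (method == "cooperative")
    run_cooperative(fn, problem$lb, problem$ub, problem$int_mask,
                    n_islands = n_islands, max_evals = max_evals,
                    max_time = max_time, vtr = vtr, seed = seed,
                    active_coords = act, ...)
  else
    ess_run(fn, problem$lb, problem$ub, problem$int_mask,
            max_evals = max_evals, max_time = max_time, vtr = vtr,
            seed = seed, active_coords = act, ...)
  elapsed <- proc.time()[["elapsed"]] - t0
  x <- res$x
  F <- objective(x, problem)
  K <- count_active_params(x, problem)
  dec <- decode_decision(x, problem)
  structure(list(call = cl, problem = problem, criterion = criterion,
                 method = method, decision = x, params = dec,
                 w = dec$w, F = F, K = K,
                 aic = suppressWarnings(aic(K, problem$n_data,
                                            max(F, aic_f_floor))),
                 aic_f_floor = aic_f_floor,
                 result = res, seed = seed, elapsed = elapsed),
            class = "logic_ode_fit")
}

#' Reduce a fitted model by AIC
#'
#' Re-optimizes the structure and parameters under the Akaike information
#' criterion so that active parameters must pay for themselves; spurious
#' hyperedges that do not reduce the data mismatch are dropped.
#'
#' @param fit a \code{logic_ode_fit}
#' @param ... overrides passed to \code{\link{logic_ode_fit}} (stopping
#'   criteria, seed, ...)
#' @return a new \code{logic_ode_fit} with \code{criterion = "aic"}
#' @export
reduce_model <- function(fit, ...) {
  stopifnot(inherits(fit, "logic_ode_fit"))
  args <- list(network = fit$problem$hypergraph,
               data = fit$problem$experiments, criterion = "aic",
               method = fit$method,
               aic_f_floor = fit$aic_f_floor)
  args <- utils::modifyList(args, list(...))
  do.call(logic_ode_fit, args)
}

# fitted model object for a decision
.fit_model <- function(fit) {
  .decision_model(fit$params, fit$problem)
}

#' @export
print.logic_ode_fit <- function(x, ...) {
  cat("Logic-based ODE model fit (", x$method, ", criterion = ",
      x$criterion, ")\n", sep = "")
  cat("  hyperedges selected: ", sum(x$w), " / ", length(x$w), "\n",
      sep = "")
  cat("  F (sum of squared residuals): ", format(x$F), " over ",
      x$problem$n_data, " measurements\n", sep = "")
  cat("  K (active parameters): ", x$K, ";  AIC: ", format(x$aic), "\n",
      sep = "")
  cat("  evaluations: ", x$result$neval, ";  stopped by: ",
      x$result$stopped_by, "\n", sep = "")
  invisible(x)
}

#' @export
summary.logic_ode_fit <- function(object, ...) {
  hg <- object$problem$hypergraph
  sel <- which(object$w == 1)
  gates <- do.call(rbind, lapply(sel, function(i) {
    e <- hg$hyperedges[[i]]
    gp <- object$params$gate_params[[i]]
    data.frame(hyperedge = i, target = e$target,
               gate = paste(ifelse(e$inputs$sign > 0, "", "!"),
                            e$inputs$species, sep = "", collapse = " & "),
               n = paste(signif(gp[, 1L], 3), collapse = ","),
               k = paste(signif(gp[, 2L], 3), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  r <- residuals(object)
  out <- list(fit = object, gates = gates, tau = object$params$tau,
              resid_sd = stats::sd(unlist(r), na.rm = TRUE))
  class(out) <- "summary.logic_ode_fit"
  out
}

#' @export
print.summary.logic_ode_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSelected gates:\n")
  print(x$gates, row.names = FALSE)
  cat("\nLife-times tau:\n")
  print(signif(x$tau, 3))
  cat("\nResidual sd: ", format(signif(x$resid_sd, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.logic_ode_fit <- function(object, active_only = TRUE, ...) {
  x <- object$decision
  names(x) <- c(object$problem$cont_names, object$problem$int_names)
  if (!active_only) return(x)
  keep_e <- which(object$w == 1)
  pat <- c(sprintf("^[nk]\\|e(%s)\\|", paste(keep_e, collapse = "|")),
           "^tau\\|", "^x0\\|", "^w\\|")
  x[grepl(paste(pat, collapse = "|"), names(x))]
}

#' @export
predict.logic_ode_fit <- function(object, experiments = NULL,
                                  type = c("observed", "trajectory"), ...) {
  type <- match.arg(type)
  if (is.null(experiments)) experiments <- object$problem$experiments
  if (inherits(experiments, "lg_experiment"))
    experiments <- list(experiments)
  model <- .fit_model(object)
  trs <- lapply(experiments, function(e) simulate_model(model, e))
  if (type == "trajectory") return(trs)
  lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    if (tr$status != "success") return(NULL)
    tr$states[, experiments[[i]]$observed, drop = FALSE]
  })
}

#' @export
fitted.logic_ode_fit <- function(object, ...) predict(object)

#' @export
residuals.logic_ode_fit <- function(object, ...) {
  yhat <- predict(object)
  lapply(seq_along(yhat), function(i) {
    e <- object$problem$experiments[[i]]
    if (is.null(e$ybar) || is.null(yhat[[i]])) return(NULL)
    e$ybar - yhat[[i]]
  })
}

#' Simulate replicate datasets from a fitted model
#'
#' @param object a \code{logic_ode_fit}
#' @param nsim number of replicate datasets
#' @param seed optional RNG seed
#' @param noise_rel measurement noise sd on the [0,1] scale (clamped to
#'   the range after adding noise)
#' @param ... unused
#' @return list of nsim datasets, each a list of experiments with
#'   simulated \code{ybar}
#' @export
simulate.logic_ode_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_rel = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  clean <- predict(object)
  experiments <- object$problem$experiments
  lapply(seq_len(nsim), function(r)
    lapply(seq_along(experiments), function(i) {
      e <- experiments[[i]]
      y <- clean[[i]]
      if (!is.null(y))
        e$ybar <- pmin(pmax(y + stats::rnorm(length(y), sd = noise_rel),
                            0), 1)
      e
    }))
}

#' Plot a fitted model
#'
#' \code{type = "convergence"} draws the best-objective-so-far curve(s)
#' against evaluations (one line per island for cooperative fits);
#' \code{type = "fit"} overlays fitted trajectories on the measurements of
#' one experiment.
#'
#' @param x a \code{logic_ode_fit}
#' @param type \code{"convergence"} or \code{"fit"}
#' @param which experiment index for \code{type = "fit"}
#' @param ... further graphical parameters
#' @export
plot.logic_ode_fit <- function(x, type = c("convergence", "fit"),
                               which = 1L, ...) {
  type <- match.arg(type)
  if (type == "convergence") {
    logs <- if (!is.null(x$result$island_logs)) x$result$island_logs
            else list(x$result$log)
    logs <- Filter(function(l) !is.null(l) && nrow(l) > 0, logs)
    fb <- unlist(lapply(logs, `[[`, "fbest"))
    graphics::plot(NA, xlim = range(unlist(lapply(logs, `[[`, "neval"))),
                   ylim = range(fb[is.finite(fb)]),
                   xlab = "objective evaluations", ylab = "best objective",
                   log = if (all(fb > 0, na.rm = TRUE)) "y" else "", ...)
    for (i in seq_along(logs))
      graphics::lines(logs[[i]]$neval, logs[[i]]$fbest, type = "s",
                      col = i)
  } else {
    e <- x$problem$experiments[[which]]
    model <- .fit_model(x)
    tt <- seq(0, max(e$times), length.out = 101L)
    dense <- experiment(stimuli = e$stimuli, inhibitors = e$inhibitors,
                        observed = e$observed,
                        times = if (tt[2] > 0) tt[-1] else tt, id = e$id)
    tr <- simulate_model(model, dense)
    graphics::matplot(tr$times, tr$states[, e$observed, drop = FALSE],
                      type = "l", lty = 1, xlab = "time",
                      ylab = "normalized state", ylim = c(0, 1), ...)
    if (!is.null(e$ybar))
      graphics::matpoints(e$times, e$ybar, pch = 16)
    graphics::legend("topright", legend = e$observed, lty = 1,
                     col = seq_along(e$observed), bty = "n", cex = 0.8)
  }
  invisible(x)
}
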