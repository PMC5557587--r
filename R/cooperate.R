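#' Cooperative island protocol
#'
#' A master process gates the exchange of solutions between eSS islands: an
#' incoming solution is broadcast only when it improves the shared
#' best-known solution by more than an adaptive relative threshold epsilon.
#' The master keeps a scoreboard of which islands produced accepted
#' solutions and, on a stagnation request, reassigns a stagnated island the
#' settings of the best-scoring island and re-diversifies most of its
#' RefSet.  All exchange goes through an in-process deterministic transport,
#' which makes cooperative runs exactly reproducible under a fixed seed.
#'
#' @name cooperation
NULL

.tiny <- 1e-300

.rel_improvement <- function(f_ref, f_new) {
  if (!is.finite(f_ref)) return(if (is.finite(f_new)) Inf else 0)
  (f_ref - f_new) / max(abs(f_ref), .tiny)
}

#' Master state of the cooperation protocol
#'
#' @param islands island identifiers
#' @param catalog list of \code{\link{ess_settings}}, one per island
#' @param eps_init initial acceptance threshold (relative improvement)
#' @param eps_floor lower bound on the threshold
#' @param halve_after consecutive refusals before the threshold is halved
#' @return master-state list
#' @export
master_state <- function(islands, catalog, eps_init = 0.1, eps_floor = 0.01,
                         halve_after = 10L) {
  list(best_f = Inf, best_x = NULL, eps = eps_init, eps_floor = eps_floor,
       eps_init = eps_init, halve_after = as.integer(halve_after),
       refusals = 0L,
       scoreboard = stats::setNames(rep(0L, length(islands)), islands),
       settings = stats::setNames(catalog[seq_along(islands)], islands),
       catalog = catalog, rr = 0L)
}

#' Master-side acceptance of an incoming solution
#'
#' Accepts iff the relative improvement over the current best-known solution
#' exceeds the master threshold.  On acceptance the best-known solution is
#' updated (to be broadcast to all islands), the sender's scoreboard entry
#' is incremented and the refusal counter reset; on refusal the counter
#' grows and the threshold adapts (\code{\link{adapt_epsilon}}).
#'
#' @param f,x incoming objective value and solution
#' @param sender island id
#' @param state master state
#' @return list(decision = "broadcast"|"refuse", state)
#' @export
master_accept <- function(f, x, sender, state) {
  if (.rel_improvement(state$best_f, f) > state$eps) {
    state$best_f <- f; state$best_x <- x
    state$scoreboard[sender] <- state$scoreboard[sender] + 1L
    state$refusals <- 0L
    list(decision = "broadcast", state = state)
  } else {
    state$refusals <- state$refusals + 1L
    state <- adapt_epsilon(state)
    list(decision = "refuse", state = state)
  }
}

#' Adapt the master acceptance threshold
#'
#' After every \code{halve_after} (default 10) consecutive refusals the
#' threshold is halved, never dropping below the floor; any acceptance
#' resets the refusal counter.
#'
#' @param state master state
#' @return updated master state
#' @export
adapt_epsilon <- function(state) {
  if (state$refusals >= state$halve_after) {
    state$eps <- max(state$eps / 2, state$eps_floor)
    state$refusals <- 0L
  }
  state
}

#' Should a slave send its new local best to the master?
#'
#' True iff the relative improvement of the new local best over the slave's
#' view of the shared best-known solution strictly exceeds the slave
#' threshold (smaller than the master's, so that many promising solutions
#' are offered).
#'
#' @param state slave state (list with \code{best_known}, \code{eps_slave})
#' @param f_new new local best objective value
#' @return logical
#' @export
slave_should_send <- function(state, f_new) {
  .rel_improvement(state$best_known, f_new) > state$eps_slave
}

#' Slave-side stagnation test
#'
#' A slave declares stagnation when BOTH printed criteria hold: it has spent
#' more than \code{Npar x 500} evaluations since its last cooperation, AND
#' it has received significantly more solutions than it sent
#' (\code{recv > 4 x sent + 10}).  On stagnation a non-blocking
#' reconfiguration request is sent and the slave keeps searching.
#'
#' @param state slave state with \code{neval_since}, \code{npar},
#'   \code{recv}, \code{sent}
#' @return logical
#' @export
stagnation_check <- function(state) {
  state$neval_since > state$npar * 500 &&
    state$recv > 4 * state$sent + 10
}

#' Assign settings to a stagnated island
#'
#' Returns the settings of the highest-scoring island other than the
#' requester (ties broken by lowest island id).  If every score is zero, a
#' fresh catalog entry is handed out round-robin.
#'
#' @param state master state
#' @param requester island id
#' @return list(settings, state)
#' @export
master_assign_settings <- function(state, requester) {
  sb <- state$scoreboard[setdiff(names(state$scoreboard), requester)]
  if (length(sb) && max(sb) > 0L) {
    top <- names(sb)[which.max(sb)]  # which.max: first max = lowest id
    list(settings = state$settings[[top]], state = state)
  } else {
    state$rr <- state$rr + 1L
    k <- ((state$rr - 1L) %% length(state$catalog)) + 1L
    list(settings = state$catalog[[k]], state = state)
  }
}

#' Reconfigure a stagnated island
#'
#' Adopts the assigned settings, retains exactly two RefSet members -- the
#' island's best local solution and the cooperative best-known solution
#' (deduplicated; the next-best local member substitutes if they coincide)
#' -- re-diversifies the remaining slots and resets the stagnation
#' counters.
#'
#' @param island island environment (from the cooperative runner)
#' @param assigned an \code{\link{ess_settings}}
#' @return the island (modified in place), invisibly
#' @export
reconfigure <- function(island, assigned) {
  st <- island$ess
  st$settings <- assigned
  dim_new <- assigned$dim_refset
  keep_X <- st$best_x
  keep_f <- st$best_f
  coop <- island$best_known_x
  if (!is.null(coop) && !all(coop == st$best_x)) {
    keep_X <- rbind(keep_X, coop)
    keep_f <- c(keep_f, island$best_known)
  } else {
    # substitute the second-best current member so exactly 2 are retained
    R <- st$refset
    alt <- which(apply(R$X, 1L, function(r) !all(r == st$best_x)))[1L]
    if (!is.na(alt)) {
      keep_X <- rbind(keep_X, R$X[alt, ])
      keep_f <- c(keep_f, R$f[alt])
    }
  }
  keep_X <- matrix(keep_X, ncol = length(st$lb))
  n_fresh <- dim_new - nrow(keep_X)
  fresh <- diversify(st$lb, st$ub, st$int_mask, n_fresh)
  fresh_f <- apply(fresh, 1L, st$evaluate)
  X <- rbind(keep_X, fresh); f <- c(keep_f, fresh_f)
  ord <- order(f)
  st$refset <- list(X = X[ord, , drop = FALSE], f = f[ord],
                    age = rep(0L, length(f)))
  island$neval_since <- 0L
  island$recv <- 0L
  island$sent <- 0L
  island$awaiting_settings <- FALSE
  invisible(island)
}

# ---- deterministic in-process transport ---------------------------------

sim_transport <- function() {
  env <- new.env(parent = emptyenv())
  env$queues <- list()
  env$seq <- list()
  env$send <- function(from, to, kind, payload = NULL) {
    key <- paste0(from, ">", to)
    s <- (env$seq[[from]] %||% 0L) + 1L
    env$seq[[from]] <- s
    msg <- list(kind = kind, sender = from, payload = payload, seq = s)
    env$queues[[key]] <- c(env$queues[[key]], list(msg))
    invisible(msg)
  }
  env$recv <- function(from, to) {
    key <- paste0(from, ">", to)
    q <- env$queues[[key]]
    env$queues[[key]] <- list()
    q %||% list()
  }
  env$pending <- function() sum(lengths(env$queues))
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Catalog of diverse island settings
#'
#' Varies the RefSet size, the local-search schedule and the
#' quality-vs-diversity balance of the RefSet build, assigned round-robin,
#' so that parallel islands explore with genuinely different
#' configurations.
#'
#' @param n number of entries
#' @return list of \code{\link{ess_settings}}
#' @export
settings_catalog <- function(n) {
  base <- list(
    ess_settings(dim_refset = 10L, local_search = "aggressive",
                 balance = 0.5),
    ess_settings(dim_refset = 8L, local_search = "conservative",
                 local_every = 5L, balance = 0.3),
    ess_settings(dim_refset = 14L, local_search = "aggressive",
                 balance = 0.7),
    ess_settings(dim_refset = 10L, local_search = "conservative",
                 local_every = 3L, balance = 0.5))
  base[((seq_len(n) - 1L) %% length(base)) + 1L]
}

#' Run the cooperative island search
#'
#' Launches \code{n_islands} eSS searches with settings drawn from the
#' catalog plus a master gating solution exchange.  Scheduling is an
#' in-process deterministic interleaving (seeded island order each round),
#' so a fixed seed reproduces the run exactly.  Any island reaching a
#' stopping criterion triggers global termination; the global best over all
#' islands and the cooperation channel is returned with per-island
#' convergence logs.
#'
#' @param fn objective function
#' @param lb,ub bounds
#' @param int_mask logical mask of integer coordinates
#' @param n_islands number of islands (>= 1)
#' @param catalog list of \code{\link{ess_settings}}; default
#'   \code{settings_catalog(n_islands)}
#' @param max_evals total objective evaluations across islands
#' @param max_time wall-clock limit (seconds)
#' @param vtr value-to-reach
#' @param seed RNG seed
#' @param eps_init,eps_floor,eps_slave cooperation thresholds (relative
#'   improvement); the slave threshold is smaller than the master's initial
#'   one
#' @param penalty finite substitute for failed evaluations
#' @param active_coords optional coordinate-dependence mask function passed
#'   to \code{\link{local_refine_mixed}}
#' @return object of class \code{coop_result}: list(x, f, neval, island
#'   logs, master summary)
#' @export
run_cooperative <- function(fn, lb, ub, int_mask = rep(FALSE, length(lb)),
                            n_islands = 4L, catalog = NULL,
                            max_evals = NULL, max_time = NULL, vtr = NULL,
                            seed = NULL, eps_init = 0.1, eps_floor = 0.01,
                            eps_slave = 0.01, penalty = 1e10,
                            active_coords = NULL) {
  if (is.null(max_evals) && is.null(max_time) && is.null(vtr))
    stop("set at least one stopping criterion (max_evals, max_time, vtr)")
  if (n_islands < 1L) stop("n_islands must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(catalog)) catalog <- settings_catalog(n_islands)
  ids <- sprintf("island%d", seq_len(n_islands))
  master <- master_state(ids, catalog, eps_init, eps_floor)
  transport <- sim_transport()
  t_start <- proc.time()[["elapsed"]]
  npar <- length(lb)

  islands <- lapply(seq_len(n_islands), function(i) {
    ev <- make_evaluator(fn, lb, ub, int_mask, penalty)
    isl <- new.env(parent = emptyenv())
    isl$id <- ids[i]
    isl$evaluate <- ev
    isl$ess <- ess_new(ev, lb, ub, int_mask, catalog[[i]],
                       t_start = t_start, active_coords = active_coords)
    isl$best_known <- Inf
    isl$best_known_x <- NULL
    isl$eps_slave <- eps_slave
    isl$npar <- npar
    isl$neval_since <- 0L
    isl$recv <- 0L
    isl$sent <- 0L
    isl$awaiting_settings <- FALSE
    isl$alive <- TRUE
    isl
  })
  names(islands) <- ids

  total_evals <- function() sum(vapply(islands, function(i)
    eval_count(i$evaluate), 1L))
  global_best <- function() {
    fb <- vapply(islands, function(i) i$ess$best_f, 1.0)
    j <- which.min(fb)
    list(f = min(fb[j], master$best_f),
         x = if (master$best_f < fb[j]) master$best_x
             else islands[[j]]$ess$best_x)
  }
  stopped <- function() {
    gb <- global_best()$f
    if (!is.null(vtr) && gb <= vtr) return("vtr")
    if (!is.null(max_evals) && total_evals() >= max_evals)
      return("max_evals")
    if (!is.null(max_time) &&
        proc.time()[["elapsed"]] - t_start >= max_time) return("max_time")
    NULL
  }

  master_step <- function() {
    for (isl in islands) {
      for (msg in transport$recv(isl$id, "master")) {
        if (msg$kind == "solution") {
          res <- master_accept(msg$payload$f, msg$payload$x, msg$sender,
                               master)
          master <<- res$state
          if (res$decision == "broadcast")
            for (other in ids)
              transport$send("master", other, "solution",
                             list(f = master$best_f, x = master$best_x))
        } else if (msg$kind == "reconfig_request") {
          res <- master_assign_settings(master, msg$sender)
          master <<- res$state
          transport$send("master", msg$sender, "settings_assignment",
                         res$settings)
        } else if (msg$kind == "terminate") {
          for (other in setdiff(ids, msg$sender))
            transport$send("master", other, "terminate")
          return("terminate")
        }
      }
    }
    NULL
  }

  slave_step <- function(isl) {
    # reception: best-known updates, reconfiguration, termination
    for (msg in transport$recv("master", isl$id)) {
      if (msg$kind == "solution") {
        isl$recv <- isl$recv + 1L
        if (msg$payload$f < isl$best_known) {
          isl$best_known <- msg$payload$f
          isl$best_known_x <- msg$payload$x
          # cooperative solution enters the RefSet
          up <- refset_update(isl$ess$refset,
                              matrix(msg$payload$x, nrow = 1L),
                              msg$payload$f, isl$ess$memory, lb, ub,
                              int_mask, isl$evaluate, isl$ess$settings)
          isl$ess$refset <- up$refset; isl$ess$memory <- up$memory
          .ess_note_best(isl$ess, msg$payload$x, msg$payload$f)
        }
      } else if (msg$kind == "settings_assignment") {
        reconfigure(isl, msg$payload)
      } else if (msg$kind == "terminate") {
        isl$alive <- FALSE
      }
    }
    if (!isl$alive) return(invisible(NULL))
    n0 <- eval_count(isl$evaluate)
    ok <- tryCatch({ ess_iterate(isl$ess); TRUE },
                   error = function(e) FALSE)
    if (!ok) { isl$alive <- FALSE; return(invisible(NULL)) }
    isl$neval_since <- isl$neval_since + (eval_count(isl$evaluate) - n0)
    # cooperation: offer a sufficiently improving local best
    if (slave_should_send(list(best_known = isl$best_known,
                               eps_slave = isl$eps_slave),
                          isl$ess$best_f)) {
      isl$best_known <- isl$ess$best_f
      isl$best_known_x <- isl$ess$best_x
      transport$send(isl$id, "master", "solution",
                     list(f = isl$ess$best_f, x = isl$ess$best_x))
      isl$sent <- isl$sent + 1L
      isl$neval_since <- 0L
    }
    # adaptive step: stagnation triggers a non-blocking reconfig request
    if (!isl$awaiting_settings &&
        stagnation_check(list(neval_since = isl$neval_since,
                              npar = isl$npar, recv = isl$recv,
                              sent = isl$sent))) {
      transport$send(isl$id, "master", "reconfig_request")
      isl$awaiting_settings <- TRUE
    }
    invisible(NULL)
  }

  why <- stopped()
  while (is.null(why)) {
    order_ids <- if (n_islands > 1L) sample(ids) else ids
    for (id in order_ids) {
      if (islands[[id]]$alive) slave_step(islands[[id]])
      res <- master_step()
      why <- stopped()
      if (!is.null(why) || identical(res, "terminate")) break
    }
    if (is.null(why) &&
        !any(vapply(islands, function(i) i$alive, TRUE)))
      stop("all islands crashed")
  }
  # drain the channel so every queued message is processed or discarded
  for (isl in islands) transport$recv("master", isl$id)
  for (isl in islands) transport$recv(isl$id, "master")

  gb <- global_best()
  logs <- lapply(islands, function(i)
    do.call(rbind, lapply(i$ess$log, as.data.frame)))
  structure(list(x = gb$x, f = gb$f, neval = total_evals(),
                 stopped_by = why,
                 island_logs = logs,
                 scoreboard = master$scoreboard,
                 eps_final = master$eps,
                 best_known_f = master$best_f,
                 iter = sum(vapply(islands, function(i) i$ess$iter, 1L))),
            class = "coop_result")
}

#' @export
print.coop_result <- function(x, ...) {
  cat("Cooperative eSS result: f = ", format(x$f), " after ", x$neval,
      " total evaluations (stopped by ", x$stopped_by, ")\n", sep = "")
  cat("  scoreboard: ",
      paste(names(x$scoreboard), x$scoreboard, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run summary as JSON
#'
#' Writes fbest, iterations, evaluations, elapsed time and whether the
#' value-to-reach was hit.
#'
#' @param result an \code{ess_result} or \code{coop_result}
#' @param path output path
#' @param vtr the value-to-reach used (optional)
#' @param elapsed wall-clock seconds (optional)
#' @export
write_run_summary <- function(result, path, vtr = NULL, elapsed = NA) {
  s <- list(fbest = result$f, iter = result$iter, evals = result$neval,
            time = elapsed,
            hit = if (!is.null(vtr)) result$f <= vtr else NA)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
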