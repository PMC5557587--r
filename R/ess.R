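#' Settings of the enhanced scatter search
#'
#' The defaults are the centre of the settings catalog used by the
#' cooperative islands: a small reference set, population an order of
#' magnitude larger, aggressive intensification (local search on every
#' improvement of the best member).
#'
#' @param dim_refset reference-set size (even, >= 4)
#' @param population diversification-set size; default 10 x dimension,
#'   capped at 200, never below 2 x dim_refset
#' @param offspring offspring generated per RefSet pair
#' @param local_search one of \code{"aggressive"} (refine every new best),
#'   \code{"conservative"} (refine every \code{local_every}-th iteration) or
#'   \code{"off"}
#' @param local_every iteration period of conservative local search
#' @param local_budget max objective evaluations per local refinement
#' @param balance fraction of the RefSet filled by quality (the rest by
#'   greedy max-min diversity)
#' @param max_age iterations a member may stagnate before replacement
#' @param dup_threshold duplicate-rejection distance, as a fraction of the
#'   scaled box diagonal
#' @param bin_flip_prob per-bit flip probability after uniform crossover;
#'   default 1/max(1, number of integer coordinates)
#' @return object of class \code{ess_settings}
#' @export
ess_settings <- function(dim_refset = 10L, population = NULL, offspring = 2L,
                         local_search = c("aggressive", "conservative", "off"),
                         local_every = 10L, local_budget = 250L,
                         balance = 0.5, max_age = 20L, dup_threshold = 1e-3,
                         bin_flip_prob = NULL) {
  dim_refset <- as.integer(dim_refset)
  if (dim_refset < 4L || dim_refset %% 2L != 0L)
    stop("dim_refset must be even and >= 4")
  local_search <- match.arg(local_search)
  structure(list(dim_refset = dim_refset, population = population,
                 offspring = as.integer(offspring),
                 local_search = local_search,
                 local_every = as.integer(local_every),
                 local_budget = as.integer(local_budget),
                 balance = balance, max_age = as.integer(max_age),
                 dup_threshold = dup_threshold,
                 bin_flip_prob = bin_flip_prob),
            class = "ess_settings")
}

# ---- evaluation wrapper --------------------------------------------------

#' Counting, auditing objective evaluator
#'
#' Wraps an objective so that every call is counted, bounds and integrality
#' are asserted on every evaluated point (no relaxation of integers, ever),
#' and non-finite values are mapped to a finite penalty.
#'
#' @param fn objective function of a numeric vector
#' @param lb,ub bounds
#' @param int_mask logical mask of integer coordinates
#' @param penalty value substituted for non-finite objective results
#' @return function with environment fields \code{count} and \code{fbest}
#' @export
make_evaluator <- function(fn, lb, ub, int_mask, penalty = 1e10) {
  count <- 0L
  fbest <- Inf
  ev <- function(x) {
    if (any(x < lb - 1e-9) || any(x > ub + 1e-9))
      stop("evaluation outside bounds")
    if (any(x[int_mask] != round(x[int_mask])))
      stop("integer coordinate evaluated at a fractional value")
    count <<- count + 1L
    f <- fn(x)
    if (!is.finite(f)) f <- penalty
    if (f < fbest) fbest <<- f
    f
  }
  ev
}

#' @rdname make_evaluator
#' @param ev an evaluator returned by \code{make_evaluator}
#' @export
eval_count <- function(ev) environment(ev)$count

# scaled distance: continuous normalized by range, integer by Hamming
.scaled_dist <- function(x, y, lb, ub, int_mask) {
  rng <- pmax(ub - lb, .Machine$double.eps)
  dc <- if (any(!int_mask))
    sum(((x[!int_mask] - y[!int_mask]) / rng[!int_mask])^2) else 0
  di <- if (any(int_mask)) sum(x[int_mask] != y[int_mask]) else 0
  sqrt(dc + di)
}

.box_diag <- function(lb, ub) sqrt(length(lb))

# safe single draw (sample() misreads a length-1 numeric vector)
.resample1 <- function(v) v[sample.int(length(v), 1L)]

# ---- diversification -----------------------------------------------------

#' Generate a diversified population
#'
#' Continuous coordinates are stratified latin-hypercube samples across the
#' bounds; binary coordinates are fair-coin draws, wider integer ranges
#' uniform draws.  Degenerate bounds (lb = ub) pin the coordinate.
#'
#' @param lb,ub bounds
#' @param int_mask logical mask of integer coordinates
#' @param nsol number of solutions
#' @return nsol x length(lb) matrix
#' @export
diversify <- function(lb, ub, int_mask, nsol) {
  stopifnot(nsol >= 1)
  n <- length(lb)
  X <- matrix(0, nsol, n)
  cont <- which(!int_mask)
  if (length(cont)) {
    H <- lhs::randomLHS(nsol, length(cont))
    X[, cont] <- sweep(sweep(H, 2L, ub[cont] - lb[cont], "*"),
                       2L, lb[cont], "+")
  }
  for (j in which(int_mask)) {
    X[, j] <- if (lb[j] == ub[j]) lb[j]
    else sample(seq(lb[j], ub[j]), nsol, replace = TRUE)
  }
  for (j in cont) if (lb[j] == ub[j]) X[, j] <- lb[j]
  X
}

# ---- RefSet construction and update -------------------------------------

#' Build the reference set from an evaluated population
#'
#' Half (by default) of the members are the best by objective value; the
#' rest are chosen greedily by maximum minimum scaled distance to the
#' already-selected members.  A population smaller than the RefSet is
#' topped up with fresh diversified solutions.
#'
#' @param X population matrix (rows = solutions)
#' @param f objective values
#' @param dim_refset RefSet size
#' @param lb,ub,int_mask problem geometry
#' @param evaluate evaluator for top-up solutions
#' @param balance fraction filled by quality
#' @return list(X, f, age)
#' @export
build_refset <- function(X, f, dim_refset, lb, ub, int_mask,
                         evaluate = NULL, balance = 0.5) {
  if (nrow(X) < dim_refset) {
    extra <- diversify(lb, ub, int_mask, dim_refset - nrow(X))
    fe <- apply(extra, 1L, evaluate)
    X <- rbind(X, extra); f <- c(f, fe)
  }
  n_q <- max(1L, round(balance * dim_refset))
  ord <- order(f)
  sel <- ord[seq_len(min(n_q, length(ord)))]
  rest <- setdiff(ord, sel)
  while (length(sel) < dim_refset && length(rest)) {
    dmin <- vapply(rest, function(i)
      min(vapply(sel, function(j)
        .scaled_dist(X[i, ], X[j, ], lb, ub, int_mask), 1.0)), 1.0)
    pick <- rest[which.max(dmin)]
    sel <- c(sel, pick); rest <- setdiff(rest, pick)
  }
  ord2 <- order(f[sel])
  list(X = X[sel[ord2], , drop = FALSE], f = f[sel[ord2]],
       age = rep(0L, length(sel)))
}

#' Update the reference set with evaluated candidates
#'
#' A candidate replaces the worst member it improves, unless it lies within
#' the duplicate-rejection distance of a current member or of a remembered
#' (visited) local optimum.  Members whose age exceeds the threshold are
#' replaced by fresh diversified solutions (and their position remembered).
#'
#' @param refset list(X, f, age)
#' @param cand_X,cand_f candidate solutions and values
#' @param memory matrix of visited local optima (may have 0 rows)
#' @param lb,ub,int_mask problem geometry
#' @param evaluate evaluator (for replacement solutions)
#' @param settings an \code{\link{ess_settings}}
#' @return list(refset, memory)
#' @export
refset_update <- function(refset, cand_X, cand_f, memory, lb, ub, int_mask,
                          evaluate, settings) {
  thr <- settings$dup_threshold * .box_diag(lb, ub)
  improved <- rep(FALSE, nrow(refset$X))
  if (length(cand_f)) {
    for (i in order(cand_f)) {
      x <- cand_X[i, ]; fx <- cand_f[i]
      worst <- which.max(refset$f)
      if (fx >= refset$f[worst]) next
      dmem <- if (nrow(memory)) min(apply(memory, 1L, .scaled_dist, x,
                                          lb, ub, int_mask)) else Inf
      dref <- min(apply(refset$X, 1L, .scaled_dist, x, lb, ub, int_mask))
      if (dref <= thr || dmem <= thr) next
      refset$X[worst, ] <- x; refset$f[worst] <- fx
      refset$age[worst] <- 0L
      improved[worst] <- TRUE
    }
  }
  refset$age[!improved] <- refset$age[!improved] + 1L
  stale <- which(refset$age > settings$max_age &
                 seq_along(refset$f) != which.min(refset$f))
  if (length(stale)) {
    memory <- rbind(memory, refset$X[stale, , drop = FALSE])
    fresh <- diversify(lb, ub, int_mask, length(stale))
    for (r in seq_along(stale)) {
      refset$X[stale[r], ] <- fresh[r, ]
      refset$f[stale[r]] <- evaluate(fresh[r, ])
      refset$age[stale[r]] <- 0L
    }
  }
  ord <- order(refset$f, refset$age)
  list(refset = list(X = refset$X[ord, , drop = FALSE], f = refset$f[ord],
                     age = refset$age[ord]),
       memory = memory)
}

# ---- combination and intensification ------------------------------------

#' Combine a pair of RefSet members
#'
#' Continuous coordinates are sampled in biased hyper-rectangles spanning
#' the segment between the parents plus the regions beyond each of them
#' along the parent-difference direction (mass biased towards the better
#' parent), then clipped to the bounds.  Integer coordinates use uniform
#' crossover followed by a per-bit flip (probability 1/max(1, n_int) by
#' default), so they are always integral.  Identical parents fall back to a
#' mutated clone.
#'
#' @param x1,x2 parents; \code{x1} must be the better one
#' @param lb,ub,int_mask problem geometry
#' @param settings an \code{\link{ess_settings}}
#' @return matrix of \code{settings$offspring} offspring (rows)
#' @export
combine_pair <- function(x1, x2, lb, ub, int_mask, settings) {
  n <- length(x1)
  n_int <- sum(int_mask)
  flip <- if (!is.null(settings$bin_flip_prob)) settings$bin_flip_prob
          else 1 / max(1L, n_int)
  identical_parents <- all(x1 == x2)
  out <- matrix(0, settings$offspring, n)
  for (o in seq_len(settings$offspring)) {
    child <- x1
    if (any(!int_mask)) {
      ix <- !int_mask
      d <- x2[ix] - x1[ix]
      if (identical_parents) {
        # perturbation fallback: jitter around the (single) parent
        child[ix] <- x1[ix] + stats::runif(sum(ix), -0.05, 0.05) *
          (ub[ix] - lb[ix])
      } else {
        # lambda < 0: beyond the better parent; [0,1]: inside the segment;
        # > 1: beyond the worse parent
        lambda <- stats::runif(sum(ix), -0.75, 1.25)
        child[ix] <- x1[ix] + lambda * d
      }
      child[ix] <- pmin(pmax(child[ix], lb[ix]), ub[ix])
    }
    if (n_int) {
      ii <- which(int_mask)
      take2 <- stats::runif(n_int) < 0.5
      child[ii] <- ifelse(take2, x2[ii], x1[ii])
      do_flip <- stats::runif(n_int) < flip
      for (j in which(do_flip)) {
        jj <- ii[j]
        if (lb[jj] == 0 && ub[jj] == 1) child[jj] <- 1 - child[jj]
        else child[jj] <- .resample1(setdiff(seq(lb[jj], ub[jj]), child[jj]))
      }
      if (identical_parents && !any(do_flip) && n_int > 0) {
        jj <- ii[sample.int(n_int, 1L)]
        child[jj] <- if (lb[jj] == 0 && ub[jj] == 1) 1 - child[jj]
                     else .resample1(setdiff(seq(lb[jj], ub[jj]), child[jj]))
      }
    }
    out[o, ] <- child
  }
  out
}

#' Go-beyond intensification
#'
#' When an offspring improves its parent, the promising direction parent ->
#' child is exploited: repeated steps (doubling in size while improvement
#' continues) are taken along the continuous part of the direction, with
#' the integer part frozen.  Stops at the first non-improvement or on bound
#' contact; never returns a point worse than the child.
#'
#' @param child,fchild improving offspring and its value
#' @param parent parent solution (with \code{fchild < f(parent)})
#' @param evaluate counting evaluator
#' @param lb,ub,int_mask problem geometry
#' @param max_steps safety cap on the number of steps
#' @return list(x, f, evals)
#' @export
go_beyond <- function(child, fchild, parent, evaluate, lb, ub, int_mask,
                      max_steps = 20L) {
  best <- child; fbest <- fchild
  ix <- !int_mask
  step <- (child - parent)[ix]
  used <- 0L
  for (s in seq_len(max_steps)) {
    if (!any(ix) || all(step == 0)) break
    cand <- best
    cand[ix] <- pmin(pmax(best[ix] + step, lb[ix]), ub[ix])
    if (all(cand == best)) break  # bound contact
    fc <- evaluate(cand); used <- used + 1L
    if (fc < fbest) {
      best <- cand; fbest <- fc
      step <- 2 * step
    } else break
  }
  list(x = best, f = fbest, evals = used)
}

# ---- mixed-integer local refinement -------------------------------------

#' Mixed-integer local refinement
#'
#' Alternates (a) bounded quasi-Newton descent (L-BFGS-B with
#' finite-difference gradients, relative step 1e-6 of the coordinate range)
#' on the continuous block at fixed integers with (b) best-improvement
#' integer neighbourhood search (all 1-flips, then 2-flips while the budget
#' allows) at the fixed continuous block, until neither improves or the
#' evaluation budget is exhausted.  The cost function is only ever evaluated
#' at integral values of the integer coordinates, and the returned point is
#' never worse than the input.
#'
#' @param x0 feasible starting point
#' @param evaluate counting evaluator
#' @param lb,ub,int_mask problem geometry
#' @param budget max objective evaluations for this refinement
#' @param f0 objective at x0 (evaluated if missing)
#' @param active_coords optional function x -> logical mask of coordinates
#'   the objective currently depends on; inactive continuous coordinates
#'   are skipped by the descent (finite-difference columns on them are
#'   exactly zero, so this only removes wasted evaluations)
#' @return list(x, f, evals)
#' @export
local_refine_mixed <- function(x0, evaluate, lb, ub, int_mask,
                               budget = 250L, f0 = NULL,
                               active_coords = NULL) {
  start <- eval_count(evaluate)
  if (is.null(f0)) f0 <- evaluate(x0)
  best <- x0; fbest <- f0
  cont_all <- which(!int_mask); ints <- which(int_mask)
  used <- function() eval_count(evaluate) - start
  repeat {
    improved <- FALSE
    cont <- if (is.null(active_coords)) cont_all
            else intersect(cont_all, which(active_coords(best)))
    # (a) continuous descent at fixed integers
    if (length(cont) && used() < budget) {
      fixed <- best
      wrap <- function(xc) {
        if (used() >= budget + 2L * length(cont)) return(fbest)  # soft stop
        z <- fixed; z[cont] <- pmin(pmax(xc, lb[cont]), ub[cont])
        evaluate(z)
      }
      ndeps <- pmax(1e-6 * (ub[cont] - lb[cont]), 1e-9)
      res <- tryCatch(
        stats::optim(best[cont], wrap, method = "L-BFGS-B",
                     lower = lb[cont], upper = ub[cont],
                     control = list(maxit = 50L, ndeps = ndeps,
                                    factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(res) && res$value < fbest - 1e-12) {
        best[cont] <- pmin(pmax(res$par, lb[cont]), ub[cont])
        fbest <- res$value
        improved <- TRUE
      }
    }
    # (b) integer neighbourhood: best-improvement 1-flips
    if (length(ints) && used() < budget) {
      repeat {
        cand_best <- NULL; cand_f <- fbest
        for (j in ints) {
          vals <- setdiff(seq(lb[j], ub[j]), best[j])
          # adjacent moves only for wide integer ranges
          if (length(vals) > 2L)
            vals <- intersect(c(best[j] - 1, best[j] + 1), vals)
          for (v in vals) {
            if (used() >= budget) break
            z <- best; z[j] <- v
            fz <- evaluate(z)
            if (fz < cand_f) { cand_best <- z; cand_f <- fz }
          }
        }
        if (is.null(cand_best)) break
        best <- cand_best; fbest <- cand_f; improved <- TRUE
        if (used() >= budget) break
      }
      # 2-flips (binary pairs), best improvement, if budget allows
      nb <- length(ints)
      if (nb >= 2L && used() + nb * (nb - 1) / 2 <= budget) {
        cand_best <- NULL; cand_f <- fbest
        for (a in seq_len(nb - 1L)) for (bq in seq((a + 1L), nb)) {
          ja <- ints[a]; jb <- ints[bq]
          if (ub[ja] - lb[ja] != 1 || ub[jb] - lb[jb] != 1) next
          z <- best
          z[ja] <- lb[ja] + ub[ja] - z[ja]
          z[jb] <- lb[jb] + ub[jb] - z[jb]
          fz <- evaluate(z)
          if (fz < cand_f) { cand_best <- z; cand_f <- fz }
        }
        if (!is.null(cand_best)) {
          best <- cand_best; fbest <- cand_f; improved <- TRUE
        }
      }
    }
    if (!improved || used() >= budget) break
  }
  list(x = best, f = fbest, evals = used())
}

# ---- the eSS engine ------------------------------------------------------

# internal state of one eSS search (used standalone and as a cooperative
# island)
ess_new <- function(evaluate, lb, ub, int_mask, settings, t_start = NULL,
                    active_coords = NULL) {
  n <- length(lb)
  npop <- settings$population
  if (is.null(npop)) npop <- min(max(10L * n, 2L * settings$dim_refset), 200L)
  npop <- max(npop, 2L * settings$dim_refset)
  X <- diversify(lb, ub, int_mask, npop)
  f <- apply(X, 1L, evaluate)
  refset <- build_refset(X, f, settings$dim_refset, lb, ub, int_mask,
                         evaluate, settings$balance)
  if (is.null(t_start)) t_start <- proc.time()[["elapsed"]]
  st <- new.env(parent = emptyenv())
  st$evaluate <- evaluate; st$lb <- lb; st$ub <- ub; st$int_mask <- int_mask
  st$settings <- settings
  st$active_coords <- active_coords
  st$refset <- refset
  st$memory <- matrix(numeric(0), 0L, n)
  st$best_x <- refset$X[1L, ]; st$best_f <- refset$f[1L]
  st$iter <- 0L
  st$t_start <- t_start
  st$log <- list(list(neval = eval_count(evaluate),
                      wall_seconds = proc.time()[["elapsed"]] - t_start,
                      fbest = st$best_f))
  st
}

.ess_note_best <- function(st, x, f) {
  if (f < st$best_f) {
    st$best_x <- x; st$best_f <- f
    st$log[[length(st$log) + 1L]] <-
      list(neval = eval_count(st$evaluate),
           wall_seconds = proc.time()[["elapsed"]] - st$t_start,
           fbest = f)
    TRUE
  } else FALSE
}

# one outer iteration (steps 3-5 + update); returns TRUE if best improved
ess_iterate <- function(st) {
  s <- st$settings
  R <- st$refset
  m <- nrow(R$X)
  cand_X <- NULL; cand_f <- numeric(0)
  improved_best <- FALSE
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    better <- if (R$f[i] <= R$f[j]) i else j
    worse <- if (better == i) j else i
    off <- combine_pair(R$X[better, ], R$X[worse, ], st$lb, st$ub,
                        st$int_mask, s)
    for (o in seq_len(nrow(off))) {
      fo <- st$evaluate(off[o, ])
      xo <- off[o, ]
      if (fo < R$f[better]) {
        gb <- go_beyond(xo, fo, R$X[better, ], st$evaluate, st$lb, st$ub,
                        st$int_mask)
        xo <- gb$x; fo <- gb$f
      }
      cand_X <- rbind(cand_X, xo); cand_f <- c(cand_f, fo)
      if (.ess_note_best(st, xo, fo)) improved_best <- TRUE
    }
  }
  do_local <- switch(s$local_search,
                     aggressive = improved_best,
                     conservative = st$iter %% s$local_every == 0L,
                     off = FALSE)
  if (do_local) {
    i0 <- which.min(cand_f)
    start_x <- if (length(cand_f)) cand_X[i0, ] else st$best_x
    start_f <- if (length(cand_f)) cand_f[i0] else st$best_f
    lr <- local_refine_mixed(start_x, st$evaluate, st$lb, st$ub,
                             st$int_mask, budget = s$local_budget,
                             f0 = start_f,
                             active_coords = st$active_coords)
    cand_X <- rbind(cand_X, lr$x); cand_f <- c(cand_f, lr$f)
    if (.ess_note_best(st, lr$x, lr$f)) improved_best <- TRUE
  }
  up <- refset_update(R, cand_X, cand_f, st$memory, st$lb, st$ub,
                      st$int_mask, st$evaluate, s)
  st$refset <- up$refset; st$memory <- up$memory
  st$iter <- st$iter + 1L
  improved_best
}

.ess_stopped <- function(st, stopping) {
  if (!is.null(stopping$vtr) && st$best_f <= stopping$vtr) return("vtr")
  if (!is.null(stopping$max_evals) &&
      eval_count(st$evaluate) >= stopping$max_evals) return("max_evals")
  if (!is.null(stopping$max_time) &&
      proc.time()[["elapsed"]] - st$t_start >= stopping$max_time)
    return("max_time")
  NULL
}

#' Run an enhanced scatter search
#'
#' Iterates diversification, RefSet combination, go-beyond intensification,
#' mixed-integer local refinement and RefSet update until a stopping
#' criterion fires.  The convergence log records (evaluations, elapsed
#' seconds, best objective) at every improvement, and the best-so-far value
#' is monotone non-increasing.
#'
#' @param fn objective function
#' @param lb,ub bounds
#' @param int_mask logical mask of integer coordinates (default all
#'   continuous)
#' @param settings an \code{\link{ess_settings}}
#' @param max_evals,max_time,vtr stopping criteria (at least one required):
#'   maximum objective evaluations, wall-clock seconds, value-to-reach
#' @param seed optional RNG seed
#' @param penalty finite substitute for non-finite objective values
#' @param active_coords optional coordinate-dependence mask function passed
#'   to \code{\link{local_refine_mixed}}
#' @return object of class \code{ess_result}: list(x, f, neval, iter, log,
#'   stopped_by)
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ess_run(sphere, rep(-1, 3), rep(1, 3), max_evals = 3000, seed = 1)
#' res$f
#' @export
ess_run <- function(fn, lb, ub, int_mask = rep(FALSE, length(lb)),
                    settings = ess_settings(), max_evals = NULL,
                    max_time = NULL, vtr = NULL, seed = NULL,
                    penalty = 1e10, active_coords = NULL) {
  if (is.null(max_evals) && is.null(max_time) && is.null(vtr))
    stop("set at least one stopping criterion (max_evals, max_time, vtr)")
  if (!is.null(seed)) set.seed(seed)
  stopping <- list(max_evals = max_evals, max_time = max_time, vtr = vtr)
  evaluate <- make_evaluator(fn, lb, ub, int_mask, penalty)
  st <- ess_new(evaluate, lb, ub, int_mask, settings,
                active_coords = active_coords)
  why <- .ess_stopped(st, stopping)
  while (is.null(why)) {
    ess_iterate(st)
    why <- .ess_stopped(st, stopping)
  }
  log <- do.call(rbind, lapply(st$log, as.data.frame))
  structure(list(x = st$best_x, f = st$best_f,
                 neval = eval_count(evaluate), iter = st$iter,
                 log = log, stopped_by = why),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat("eSS result: f = ", format(x$f), " after ", x$neval,
      " evaluations (", x$iter, " iterations; stopped by ", x$stopped_by,
      ")\n", sep = "")
  invisible(x)
}

#' Write a convergence log as CSV
#'
#' Columns \code{neval}, \code{wall_seconds}, \code{fbest} -- one row per
#' improvement of the incumbent.
#'
#' @param result an \code{ess_result} (or cooperative fit) with a
#'   \code{log} component
#' @param path output path
#' @export
write_convergence_csv <- function(result, path) {
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}
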