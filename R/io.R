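#' Read and write MIDAS-style perturbation data
#'
#' The MIDAS-like CSV holds one row per (experiment, sampling time):
#' \code{TR:<species>} columns give stimulus clamp levels,
#' \code{TR:<species>i} columns flag inhibitors (0/1), \code{DA:<species>}
#' columns give the sampling time of each measured species and
#' \code{DV:<species>} its value; a blank DV cell is a missing measurement
#' (excluded from the data count).  Rows sharing one treatment signature
#' form one experiment; within it the DA times must be strictly
#' increasing.  \code{write_midas} then \code{read_midas} reproduces the
#' in-memory experiments exactly.
#'
#' @param experiments list of \code{\link{experiment}} objects with data
#' @param path CSV path
#' @return \code{read_midas}: list of experiments
#' @export
write_midas <- function(experiments, path) {
  if (inherits(experiments, "lg_experiment")) experiments <- list(experiments)
  stim_sp <- sort(unique(unlist(lapply(experiments,
                                       function(e) names(e$stimuli)))))
  inhib_sp <- sort(unique(unlist(lapply(experiments,
                                        function(e) e$inhibitors))))
  obs <- experiments[[1L]]$observed
  for (e in experiments)
    if (!identical(e$observed, obs))
      stop("all experiments must share the same observed species")
  rows <- list()
  for (e in experiments) {
    for (ti in seq_along(e$times)) {
      row <- stats::setNames(as.list(rep(NA_real_,
                                         length(stim_sp) + length(inhib_sp) +
                                           2L * length(obs))),
                             c(sprintf("TR:%s", stim_sp),
                               sprintf("TR:%si", inhib_sp),
                               sprintf("DA:%s", obs),
                               sprintf("DV:%s", obs)))
      for (s in stim_sp)
        row[[sprintf("TR:%s", s)]] <-
          if (s %in% names(e$stimuli)) e$stimuli[[s]] else 0
      for (s in inhib_sp)
        row[[sprintf("TR:%si", s)]] <- as.numeric(s %in% e$inhibitors)
      for (o in obs) {
        row[[sprintf("DA:%s", o)]] <- e$times[ti]
        v <- if (!is.null(e$ybar)) e$ybar[ti, o] else NA_real_
        row[[sprintf("DV:%s", o)]] <- v
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  # full-precision formatting so write-then-read is exact
  df[] <- lapply(df, function(col)
    ifelse(is.na(col), NA_character_, sprintf("%.17g", col)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_midas
#' @export
read_midas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(df)
  inhib_cols <- grep("^TR:.*i$", cn, value = TRUE)
  stim_cols <- setdiff(grep("^TR:", cn, value = TRUE), inhib_cols)
  da_cols <- grep("^DA:", cn, value = TRUE)
  dv_cols <- grep("^DV:", cn, value = TRUE)
  if (!length(da_cols) || !length(dv_cols))
    stop("MIDAS file needs DA: and DV: columns")
  obs_da <- sub("^DA:", "", da_cols)
  obs_dv <- sub("^DV:", "", dv_cols)
  if (!setequal(obs_da, obs_dv))
    stop("DA:/DV: species mismatch: ",
         paste(union(setdiff(obs_da, obs_dv), setdiff(obs_dv, obs_da)),
               collapse = ", "))
  obs <- obs_da
  sig <- apply(df[, c(stim_cols, inhib_cols), drop = FALSE], 1L,
               paste, collapse = "|")
  experiments <- list()
  for (s in unique(sig)) {
    rows <- which(sig == s)
    tvals <- df[rows, da_cols, drop = FALSE]
    tv <- as.numeric(tvals[, 1L])
    if (!all(apply(tvals, 1L, function(r) all(as.numeric(r) == as.numeric(r[1L])))))
      stop("row(s) ", paste(rows, collapse = ","),
           ": DA times differ across species within one row")
    if (is.unsorted(tv, strictly = TRUE))
      stop("experiment with treatment signature '", s,
           "': DA times not strictly increasing (rows ",
           paste(rows, collapse = ","), ")")
    ybar <- matrix(as.numeric(as.matrix(df[rows, sprintf("DV:%s", obs),
                                           drop = FALSE])),
                   nrow = length(rows), dimnames = list(NULL, obs))
    stim <- vapply(stim_cols, function(cc) as.numeric(df[rows[1L], cc]), 1.0)
    names(stim) <- sub("^TR:", "", stim_cols)
    on <- vapply(inhib_cols, function(cc) as.numeric(df[rows[1L], cc]) > 0,
                 TRUE)
    inhibitors <- sub("^TR:(.*)i$", "\\1", inhib_cols[on])
    experiments[[length(experiments) + 1L]] <-
      experiment(stimuli = stim, inhibitors = inhibitors, observed = obs,
                 times = tv, ybar = ybar,
                 id = sprintf("e%02d", length(experiments) + 1L))
  }
  experiments
}

#' Write / read the ground truth as JSON
#'
#' Stores the prior edges, the true selector by hyperedge id, the true
#' parameters (named by species / hyperedge input) and the perturbable
#' species -- everything needed to grade a recovered structure.
#'
#' @param truth a \code{ground_truth}
#' @param path JSON path
#' @export
write_truth_json <- function(truth, path) {
  gp <- lapply(seq_along(truth$gate_params), function(i) {
    e <- truth$hypergraph$hyperedges[[i]]
    list(target = e$target, inputs = e$inputs$species,
         signs = e$inputs$sign,
         n = unname(truth$gate_params[[i]][, 1L]),
         k = unname(truth$gate_params[[i]][, 2L]))
  })
  jsonlite::write_json(
    list(edges = truth$edges, w = truth$w,
         hyperedges = gp, tau = as.list(truth$tau),
         x0 = as.list(truth$x0),
         stimuli = truth$stimuli, inhibitors = truth$inhibitors),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- signed_edges(j$edges$source, j$edges$target, j$edges$sign)
  j$edges <- edges
  j$w <- as.numeric(j$w)
  j$tau <- unlist(j$tau)
  j$x0 <- unlist(j$x0)
  j
}

#' Read a run configuration (JSON or YAML)
#'
#' Validates that at least one stopping criterion is present and fills in
#' defaults for the solver settings.
#'
#' @param path configuration file (.json, .yml or .yaml)
#' @return named list (class \code{run_config})
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$max_evals) && is.null(cfg$max_time) && is.null(cfg$vtr))
    stop("configuration must set at least one stopping criterion ",
         "(max_evals, max_time, vtr)")
  defaults <- list(islands = 4L, seed = 1L, transport = "sim",
                   max_and_order = 2L, criterion = "sse")
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, package version and the decision-vector
#' encoding map -- sufficient to reproduce a run exactly under the
#' deterministic in-process transport.
#'
#' @param path output JSON path
#' @param config the run configuration (list)
#' @param seed the seed used
#' @param problem optional \code{fit_problem} whose encoding map is emitted
#' @export
write_manifest <- function(path, config, seed, problem = NULL) {
  m <- list(config = config, seed = seed,
            package_version = as.character(utils::packageVersion("logicess")),
            r_version = R.version.string)
  if (!is.null(problem))
    m$encoding <- list(continuous = problem$cont_names,
                       integer = problem$int_names,
                       lb = problem$lb, ub = problem$ub)
  class(m$config) <- NULL
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
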