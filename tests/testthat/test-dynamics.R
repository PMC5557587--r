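test_that("single-state dynamics match the analytic exponential across tau", {
  hg <- expand_prior_network(signed_edges("A", "B", 1))
  for (tau in c(0.1, 1, 10)) {
    gp <- list(cbind(n = 3, k = 0.5))
    m <- logic_ode_model(hg, tau = tau, gate_params = gp, w = 1)
    # stimulus A = 1: normalized Hill of 1 is 1, so B' = (1 - B)/tau
    times <- c(0, tau / 2, tau, 5 * tau)
    ex <- experiment(stimuli = c(A = 1), observed = "B", times = times)
    tr <- simulate_model(m, ex)
    expect_equal(tr$states[, "B"], 1 - exp(-times / tau), tolerance = 1e-5)
    # all selectors off: decay from x0
    m2 <- logic_ode_model(hg, tau = tau, gate_params = gp, w = 0,
                          x0 = c(A = 0, B = 0.8))
    tr2 <- simulate_model(m2, ex)
    expect_equal(tr2$states[, "B"], 0.8 * exp(-times / tau),
                 tolerance = 1e-5)
  }
})

test_that("compiled and pure-R right-hand sides agree", {
  set.seed(21)
  for (s in 1:5) {
    rm <- random_model(seed = 300 + s)
    ex <- experiment(stimuli = setNames(rep(1, length(rm$truth$stimuli)),
                                        rm$truth$stimuli),
                     observed = character(0), times = c(0, 1, 4))
    t1 <- simulate_model(rm$model, ex, engine = "compiled")
    t2 <- simulate_model(rm$model, ex, engine = "r")
    expect_equal(t1$states, t2$states, tolerance = 1e-6)
    # and the RHS itself at a random interior point
    m <- apply_perturbations(rm$model, ex)
    rhs <- build_rhs(m)
    x <- runif(length(m$x0))
    names(x) <- names(m$x0)
    dx_r <- rhs(0, x)
    # finite check: derivative of clamped species is zero
    expect_true(all(dx_r[m$hypergraph$input_species] == 0))
  }
})

test_that("trajectories stay inside the unit box for random models and experiments", {
  set.seed(22)
  for (s in 1:50) {
    rm <- random_model(seed = 400 + s)
    stim_lvl <- round(runif(length(rm$truth$stimuli)))
    inhib <- if (length(rm$truth$inhibitors) && runif(1) < 0.5)
      rm$truth$inhibitors else character(0)
    ex <- experiment(stimuli = setNames(stim_lvl, rm$truth$stimuli),
                     inhibitors = inhib, times = c(0, 0.5, 2, 8, 20))
    tr <- simulate_model(rm$model, ex)
    expect_identical(tr$status, "success")
    expect_true(min(tr$states) >= -1e-6)
    expect_true(max(tr$states) <= 1 + 1e-6)
  }
})

test_that("states converge to the fixed point of their gate value on long horizons", {
  # A clamped at 0.6 drives B through a single Hill gate: B* = f(0.6)
  hg <- expand_prior_network(signed_edges("A", "B", 1))
  gp <- list(cbind(n = 2, k = 0.5))
  m <- logic_ode_model(hg, tau = 1, gate_params = gp, w = 1)
  ex <- experiment(stimuli = c(A = 0.6), observed = "B", times = c(0, 60))
  tr <- simulate_model(m, ex)
  expect_equal(unname(tr$states[2, "B"]), normalized_hill(0.6, 2, 0.5),
               tolerance = 1e-4)
})

test_that("stimulus clamps hold bit-identically and inhibition forces exponential decay", {
  m <- chain_model(tau = 1)
  ex <- experiment(stimuli = c(A = 0.7), inhibitors = "B",
                   observed = c("B", "C"), times = c(0, 0.5, 1, 2))
  m2 <- apply_perturbations(m, ex)
  m2$x0["B"] <- 0.5
  tr <- simulate_model(m2, ex)
  expect_identical(unname(tr$states[, "A"]), rep(0.7, 4))
  # inhibited node: B-bar forced to 0 so x_B = 0.5 exp(-t)
  expect_equal(tr$states[, "B"], 0.5 * exp(-c(0, 0.5, 1, 2)),
               tolerance = 1e-5)
})

test_that("perturbations validate species and leave the model untouched when empty", {
  m <- chain_model()
  expect_error(apply_perturbations(m, experiment(stimuli = c(ZZ = 1))),
               "unknown species")
  m0 <- apply_perturbations(m, experiment())
  expect_identical(m0$inhibited, character(0))
  expect_identical(unname(m0$clamped), 0)  # input A clamped at 0
})

test_that("zero-length horizons return the initial state", {
  m <- chain_model()
  m$x0["B"] <- 0.4
  ex <- experiment(times = c(0), observed = "B")
  tr <- simulate_model(m, ex)
  expect_identical(unname(tr$states[1, "B"]), 0.4)
})

test_that("trajectories export as tidy data frames", {
  m <- chain_model()
  ex <- experiment(stimuli = c(A = 1), times = c(0, 1, 2), id = "trial")
  tr <- simulate_model(m, ex)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "species", "value", "experiment"))
  expect_equal(nrow(df), 3 * 3)
  expect_true(all(df$experiment == "trial"))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_equal(read.csv(path)$value, df$value)
})
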