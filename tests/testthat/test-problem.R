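test_that("encode/decode round-trips random valid parameter sets", {
  set.seed(31)
  truth <- generate_network(seed = 31)
  bench <- generate_pseudodata(truth, noise_rel = 0)
  pr <- fit_problem(truth$hypergraph, bench$noiseless)
  for (rep in 1:10) {
    gp <- lapply(truth$hypergraph$hyperedges, function(e)
      cbind(n = runif(nrow(e$inputs), 1, 10),
            k = runif(nrow(e$inputs), 0.01, 1)))
    dyn <- setdiff(truth$hypergraph$species,
                   truth$hypergraph$input_species)
    params <- list(gate_params = gp,
                   tau = setNames(runif(length(dyn), 0.1, 10), dyn),
                   w = as.numeric(rbinom(length(truth$w), 1, 0.5)))
    x <- encode_decision(params, pr)
    dec <- decode_decision(x, pr)
    x2 <- encode_decision(dec, pr)
    expect_identical(unname(x), unname(x2))
    expect_identical(dec$w, params$w)
    expect_equal(dec$tau, params$tau)
  }
  # out-of-bounds values are refused
  params <- list(gate_params = lapply(truth$hypergraph$hyperedges,
                                      function(e)
                                        cbind(n = rep(99, nrow(e$inputs)),
                                              k = rep(0.5, nrow(e$inputs)))),
                 tau = setNames(rep(1, 4), setdiff(truth$hypergraph$species,
                                                   truth$hypergraph$input_species)),
                 w = truth$w)
  expect_error(encode_decision(params, pr), "out of bounds")
})

test_that("integer block length equals the hyperedge count and x0 entries appear only when estimated", {
  truth <- generate_network(seed = 32)
  bench <- generate_pseudodata(truth, noise_rel = 0)
  pr <- fit_problem(truth$hypergraph, bench$noiseless)
  expect_length(pr$int_names, length(truth$hypergraph$hyperedges))
  expect_false(any(grepl("^x0\\|", pr$cont_names)))
  pr2 <- fit_problem(truth$hypergraph, bench$noiseless,
                     estimate_x0 = "X1")
  expect_true("x0|X1" %in% pr2$cont_names)
  expect_identical(sum(pr2$int_mask), length(truth$w))
})

test_that("objective is zero at a perfect fit and sums squared residuals otherwise", {
  truth <- generate_network(seed = 33)
  bench <- generate_pseudodata(truth, noise_rel = 0)
  pr <- fit_problem(truth$hypergraph, bench$noiseless)
  xt <- encode_truth(truth, pr)
  expect_lt(objective(xt, pr), 1e-8)
  # single-observation check: ybar = 0.5 vs y = 0 gives 0.25
  hg <- expand_prior_network(signed_edges("A", "B", 1))
  ex <- experiment(stimuli = c(A = 0), observed = "B", times = c(0, 1),
                   ybar = matrix(c(NA, 0.5), 2, 1))
  pr1 <- fit_problem(hg, list(ex))
  x1 <- encode_decision(list(gate_params = list(cbind(n = 2, k = 0.5)),
                             tau = c(B = 1), w = 0), pr1)
  expect_equal(objective(x1, pr1), 0.25)  # B stays at 0, one residual
})

test_that("objective ignores parameters of deselected hyperedges and missing measurements", {
  set.seed(34)
  truth <- generate_network(seed = 34)
  bench <- generate_pseudodata(truth, noise_rel = 0.05, seed = 34)
  pr <- fit_problem(truth$hypergraph, bench$experiments)
  xt <- encode_truth(truth, pr)
  f0 <- objective(xt, pr)
  for (rep in 1:5) {
    x <- xt
    off <- which(truth$w == 0)
    for (e in off) {
      sel <- grepl(sprintf("^[nk]\\|e%d\\|", e), pr$cont_names)
      x[which(sel)] <- runif(sum(sel), 1, 2)  # within both n and k bounds? n in [1,10], k in [0.01,1]
      # keep k entries inside their bounds
      ksel <- grepl(sprintf("^k\\|e%d\\|", e), pr$cont_names)
      x[which(ksel)] <- runif(sum(ksel), 0.01, 1)
    }
    expect_identical(objective(x, pr), f0)
  }
  # NA insertion leaves the remaining residuals untouched
  bench2 <- bench$experiments
  bench2[[1]]$ybar[1, 1] <- NA
  pr2 <- fit_problem(truth$hypergraph, bench2)
  expect_identical(pr2$n_data, pr$n_data - 1L)
  x2 <- encode_truth(truth, pr2)
  r_removed <- bench$experiments[[1]]$ybar[1, 1] -
    simulate_model(truth_model_of(truth),
                   bench$experiments[[1]])$states[1, bench$observed[1]]
  expect_equal(objective(x2, pr2), unname(f0 - r_removed^2),
               tolerance = 1e-10)
})

test_that("AIC follows 2K + 2n log(F/n) with the standard variant available", {
  expect_equal(aic(K = 3, n = 10, F = 10), 6)      # log term vanishes
  expect_equal(aic(K = 0, n = 7, F = 7), 0)
  expect_equal(aic(K = 5, n = 100, F = 50), 10 + 200 * log(0.5))
  expect_equal(standard_aic(K = 5, n = 100, F = 50),
               100 * log(0.5) + 10)
  expect_warning(v <- aic(K = 2, n = 5, F = 0), "perfect fit")
  expect_identical(v, -Inf)
  # removing a spurious edge at unchanged F strictly lowers the AIC
  expect_lt(aic(K = 10, n = 50, F = 2), aic(K = 13, n = 50, F = 2))
})

test_that("active-parameter counting follows the 2(n,k) + tau + w rule", {
  hg <- expand_prior_network(signed_edges(c("A", "B"), c("C", "C"),
                                          c(1, 1)))
  ex <- experiment(stimuli = c(A = 0, B = 0), observed = "C",
                   times = c(0, 1), ybar = matrix(c(0, 0), 2, 1))
  pr <- fit_problem(hg, list(ex))
  base <- list(gate_params = lapply(hg$hyperedges, function(e)
    cbind(n = rep(2, nrow(e$inputs)), k = rep(0.5, nrow(e$inputs)))),
    tau = c(C = 1))
  # all deselected: K = 0
  x0 <- encode_decision(c(base, list(w = c(0, 0, 0))), pr)
  expect_identical(count_active_params(x0, pr), 0L)
  # the single 2-input AND gate: 2x2 (n,k) + 1 tau + 1 w = 6
  and_id <- which(vapply(hg$hyperedges, function(e) nrow(e$inputs), 1L) == 2)
  w <- c(0, 0, 0); w[and_id] <- 1
  x1 <- encode_decision(c(base, list(w = w)), pr)
  expect_identical(count_active_params(x1, pr), 6L)
  # deselecting a singleton drops K by at least 3 (2 params + tau or w)
  x2 <- encode_decision(c(base, list(w = c(1, 1, 0))), pr)
  x3 <- encode_decision(c(base, list(w = c(1, 0, 0))), pr)
  expect_gte(count_active_params(x2, pr) - count_active_params(x3, pr), 3L)
})

test_that("piecewise-constant controls materialize as right-open step functions", {
  cvp <- control_parameterization(mesh = c(0, 2), controls = "u")
  u <- parameterize_controls(cvp, levels = 0.4)[["u"]]
  expect_identical(u(c(0, 1, 2)), rep(0.4, 3))
  cvp2 <- control_parameterization(mesh = c(0, 1, 2), controls = "u")
  u2 <- parameterize_controls(cvp2, levels = c(0, 1))[["u"]]
  expect_identical(u2(0.5), 0)
  expect_identical(u2(1.5), 1)
  expect_identical(u2(1), 1)  # right-open elements
  cvpI <- control_parameterization(mesh = c(0, 1, 2), controls = "i",
                                   integer = TRUE)
  expect_error(parameterize_controls(cvpI, levels = c(0, 0.5)),
               "non-integral")
  expect_error(parameterize_controls(cvp2, levels = c(0, 1, 1)),
               "levels")
})

test_that("control levels join the decision vector and drive the simulated clamp", {
  hg <- expand_prior_network(signed_edges("A", "B", 1))
  cvp <- control_parameterization(mesh = c(0, 2, 4), controls = "A")
  ex <- experiment(stimuli = c(A = 0), observed = "B",
                   times = c(0, 2, 4),
                   ybar = matrix(c(0, 0.2, 0.4), 3, 1))
  pr <- fit_problem(hg, list(ex), cvp = cvp)
  expect_true(all(c("wu|A|el1", "wu|A|el2") %in% pr$cont_names))
  x <- encode_decision(list(
    gate_params = list(cbind(n = 2, k = 0.5)), tau = c(B = 1), w = 1,
    cvp_levels = c("wu|A|el1" = 0, "wu|A|el2" = 1)), pr)
  f <- objective(x, pr)
  expect_true(is.finite(f) && f >= 0)
  # element 1 has A = 0: B must still be ~0 at t = 2; element 2 drives it up
  dec <- decode_decision(x, pr)
  tr <- logicess:::.simulate_piecewise(
    logicess:::.decision_model(dec, pr), ex, cvp, dec$cvp_levels,
    rtol = 1e-6, atol = 1e-8)
  expect_lt(tr$states[2, "B"], 1e-4)
  expect_gt(tr$states[3, "B"], 0.5)
})
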