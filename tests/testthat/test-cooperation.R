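test_that("master acceptance gates on relative improvement and keeps the scoreboard", {
  st <- master_state(c("i1", "i2"), settings_catalog(2), eps_init = 0.1)
  # first incoming solution is always accepted (best initialized at +Inf)
  r <- master_accept(42, c(0), "i1", st)
  expect_identical(r$decision, "broadcast")
  expect_identical(r$state$best_f, 42)
  expect_identical(unname(r$state$scoreboard["i1"]), 1L)
  st <- r$state
  # 5% improvement refused under eps = 0.1
  r2 <- master_accept(42 * 0.95, c(0), "i2", st)
  expect_identical(r2$decision, "refuse")
  expect_identical(unname(r2$state$scoreboard["i2"]), 0L)
  # 20% improvement accepted and best updated monotonically
  r3 <- master_accept(42 * 0.8, c(0), "i2", r2$state)
  expect_identical(r3$decision, "broadcast")
  expect_lt(r3$state$best_f, 42)
  expect_identical(r3$state$refusals, 0L)
})

test_that("the master threshold halves after every ten consecutive refusals down to its floor", {
  st <- master_state("i1", settings_catalog(1), eps_init = 0.1,
                     eps_floor = 0.01)
  st$best_f <- 10
  for (i in 1:9) st <- master_accept(9.99, c(0), "i1", st)$state
  expect_identical(st$eps, 0.1)   # nine refusals: unchanged
  st <- master_accept(9.99, c(0), "i1", st)$state
  expect_identical(st$eps, 0.05)  # tenth refusal: halved
  for (i in 1:40) st <- master_accept(9.99, c(0), "i1", st)$state
  expect_identical(st$eps, 0.01)  # clamped at the floor
})

test_that("slaves offer solutions only above their threshold, strictly", {
  sl <- list(best_known = 10, eps_slave = 0.01)
  expect_false(slave_should_send(sl, 10 * (1 - 0.01)))  # exactly eps: kept
  expect_true(slave_should_send(sl, 9.89))              # 1.1% > 1%
  expect_true(slave_should_send(list(best_known = Inf, eps_slave = 0.01),
                                1e6))                   # first cooperation
})

test_that("stagnation needs BOTH printed criteria: Npar x 500 and 4 x sent + 10", {
  mk <- function(neval, recv, sent, npar = 100)
    list(neval_since = neval, npar = npar, recv = recv, sent = sent)
  expect_true(stagnation_check(mk(50001, 51, 10)))
  expect_false(stagnation_check(mk(49999, 1000, 0)))  # first criterion fails
  expect_false(stagnation_check(mk(50001, 10, 0)))    # 10 is not > 10
  expect_false(stagnation_check(mk(50001, 50, 10)))   # 50 is not > 50
})

test_that("settings are reassigned from the top of the scoreboard, never the requester's own", {
  cat3 <- settings_catalog(3)
  st <- master_state(c("A", "B", "C"), cat3)
  st$scoreboard[] <- c(3L, 1L, 0L)
  r <- master_assign_settings(st, "C")
  expect_identical(r$settings, st$settings[["A"]])
  r2 <- master_assign_settings(st, "A")   # top scorer asks: second ranked
  expect_identical(r2$settings, st$settings[["B"]])
  st$scoreboard[] <- 0L                   # all zero: catalog round-robin
  r3 <- master_assign_settings(st, "B")
  r4 <- master_assign_settings(r3$state, "B")
  expect_identical(r3$settings, cat3[[1]])
  expect_identical(r4$settings, cat3[[2]])
})

test_that("reconfiguration retains exactly two members and re-diversifies the rest", {
  set.seed(51)
  fx <- minlp_fixtures()[[1]]
  ev <- make_evaluator(fx$fn, fx$lb, fx$ub, fx$int_mask)
  isl <- new.env()
  isl$ess <- logicess:::ess_new(ev, fx$lb, fx$ub, fx$int_mask,
                                ess_settings(dim_refset = 10))
  isl$evaluate <- ev
  isl$best_known <- 0.5
  isl$best_known_x <- c(0.9, 1, 1, 1)
  isl$neval_since <- 999L; isl$recv <- 9L; isl$sent <- 1L
  old <- isl$ess$refset$X
  best_before <- isl$ess$best_x
  reconfigure(isl, ess_settings(dim_refset = 10))
  new <- isl$ess$refset$X
  retained <- sum(apply(new, 1, function(r)
    any(apply(old, 1, function(o) all(o == r))) ||
      all(r == isl$best_known_x)))
  expect_identical(retained, 2L)  # exactly 8 of 10 replaced
  expect_true(any(apply(new, 1, function(r) all(r == best_before))))
  expect_identical(isl$neval_since, 0L)
  expect_true(all(new >= matrix(fx$lb, nrow(new), ncol(new), byrow = TRUE) &
                    new <= matrix(fx$ub, nrow(new), ncol(new), byrow = TRUE)))
  im <- which(fx$int_mask)
  expect_true(all(new[, im] == round(new[, im])))
})

test_that("the simulated transport delivers per-link in order with increasing sequence numbers", {
  tr <- logicess:::sim_transport()
  tr$send("a", "m", "solution", list(f = 3))
  tr$send("a", "m", "solution", list(f = 2))
  tr$send("b", "m", "solution", list(f = 1))
  got <- tr$recv("a", "m")
  expect_identical(vapply(got, function(m) m$payload$f, 1.0), c(3, 2))
  expect_identical(vapply(got, function(m) m$seq, 1L), c(1L, 2L))
  expect_identical(tr$pending(), 1L)
  tr$recv("b", "m")
  expect_identical(tr$pending(), 0L)  # liveness: nothing left queued
})

test_that("a single island behaves as plain eSS plus a no-op cooperation layer", {
  f <- minlp_fixtures()[[1]]
  res <- run_cooperative(f$fn, f$lb, f$ub, f$int_mask, n_islands = 1,
                         max_evals = 4000, vtr = 1e-8, seed = 2)
  expect_lt(res$f, 1e-6)
  expect_length(res$island_logs, 1L)
})

test_that("cooperative runs are reproducible and the channel conserves the best solution", {
  f <- minlp_fixtures()[[2]]
  r1 <- run_cooperative(f$fn, f$lb, f$ub, f$int_mask, n_islands = 3,
                        max_evals = 6000, seed = 5)
  r2 <- run_cooperative(f$fn, f$lb, f$ub, f$int_mask, n_islands = 3,
                        max_evals = 6000, seed = 5)
  expect_identical(r1$f, r2$f)
  expect_identical(r1$x, r2$x)
  for (i in seq_along(r1$island_logs)) {
    expect_identical(r1$island_logs[[i]]$neval, r2$island_logs[[i]]$neval)
    expect_identical(r1$island_logs[[i]]$fbest, r2$island_logs[[i]]$fbest)
  }
  # master best never below the global best of the islands (conservation)
  expect_gte(r1$best_known_f, r1$f)
  # island logs are individually monotone
  for (l in r1$island_logs) expect_true(all(diff(l$fbest) <= 0))
})

test_that("an injected known optimum is broadcast and reaches every island", {
  # drive the protocol by hand: island i2 offers the certified optimum,
  # the master accepts and broadcasts, and every island receives it
  f <- minlp_fixtures()[[1]]
  ids <- c("i1", "i2", "i3")
  st <- master_state(ids, settings_catalog(3))
  tr <- logicess:::sim_transport()
  tr$send("i2", "master", "solution", list(f = f$fstar, x = f$xstar))
  for (msg in tr$recv("i2", "master")) {
    r <- master_accept(msg$payload$f, msg$payload$x, msg$sender, st)
    st <- r$state
    expect_identical(r$decision, "broadcast")
    for (id in ids)
      tr$send("master", id, "solution",
              list(f = st$best_f, x = st$best_x))
  }
  views <- lapply(ids, function(id) tr$recv("master", id)[[1]]$payload)
  expect_true(all(vapply(views, function(v) v$f == f$fstar, TRUE)))
  expect_identical(st$best_f, f$fstar)
})
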