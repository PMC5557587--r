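test_that("diversification stratifies continuous coordinates and keeps everything in bounds", {
  set.seed(41)
  lb <- c(0, -2, 0); ub <- c(1, 2, 1)
  int_mask <- c(FALSE, FALSE, TRUE)
  X <- diversify(lb, ub, int_mask, 100)
  # latin-hypercube property: each decile holds exactly 10 samples
  dec <- findInterval(X[, 1], seq(0, 1, by = 0.1), rightmost.closed = TRUE)
  expect_true(all(table(dec) == 10))
  expect_true(all(X[, 2] >= -2 & X[, 2] <= 2))
  # binary coordinate: fair coin, all integral
  expect_true(all(X[, 3] %in% c(0, 1)))
  expect_gte(mean(X[, 3]), 0.3)
  expect_lte(mean(X[, 3]), 0.7)
  # degenerate bounds pin the coordinate
  Xd <- diversify(c(0.5, 0), c(0.5, 1), c(FALSE, FALSE), 20)
  expect_true(all(Xd[, 1] == 0.5))
})

test_that("RefSet construction keeps the best member and fills diversity by greedy max-min", {
  set.seed(42)
  lb <- 0; ub <- 1; im <- FALSE
  ev <- make_evaluator(function(x) x^2, lb, ub, im)
  # 1-D points: after the quality half {0}, the max-min diversity pick is 1
  X <- matrix(c(0, 0.1, 0.2, 1), ncol = 1)
  f <- apply(X, 1, ev)
  rs <- build_refset(X, f, 2, lb, ub, im, ev, balance = 0.5)
  expect_identical(sort(as.vector(rs$X)), c(0, 1))
  # population of exactly dimRefSet distinct members all enter
  X2 <- matrix(seq(0, 1, length.out = 4), ncol = 1)
  f2 <- apply(X2, 1, ev)
  rs2 <- build_refset(X2, f2, 4, lb, ub, im, ev)
  expect_identical(sort(as.vector(rs2$X)), as.numeric(X2))
  expect_identical(rs2$f, sort(f2))  # best-first ordering
  # small population is topped up by fresh diversification
  rs3 <- build_refset(X[1:2, , drop = FALSE], f[1:2], 6, lb, ub, im, ev)
  expect_identical(nrow(rs3$X), 6L)
})

test_that("pair combination respects bounds, integrality and the crossover flip law", {
  set.seed(43)
  s <- ess_settings(offspring = 2)
  lb <- c(0, 0, 0); ub <- c(1, 1, 1); im <- c(FALSE, TRUE, TRUE)
  off <- replicate(200, combine_pair(c(0.2, 1, 0), c(0.8, 1, 1),
                                     lb, ub, im, s),
                   simplify = FALSE)
  O <- do.call(rbind, off)
  expect_identical(nrow(O), 400L)  # configured offspring count per pair
  expect_true(all(O >= 0 & O <= 1))
  expect_true(all(O[, 2:3] %in% c(0, 1)))
  # bit 2 is shared by both parents: it changes with frequency ~ flip rate
  flip <- 1 / 2  # two integer coordinates
  rate <- mean(O[, 2] != 1)
  expect_gt(rate, flip - 0.1)
  expect_lt(rate, flip + 0.1)
  # identical parents fall back to a perturbed clone
  off2 <- combine_pair(c(0.5, 1, 0), c(0.5, 1, 0), lb, ub, im, s)
  expect_false(all(off2[1, ] == c(0.5, 1, 0)) &&
                 all(off2[2, ] == c(0.5, 1, 0)))
})

test_that("go-beyond walks a convex valley monotonically and respects its precondition", {
  ev <- make_evaluator(function(x) (x - 1)^2, 0, 1.0, FALSE)
  parent <- 0; child <- 0.25
  res <- go_beyond(child, ev(child), parent, ev, 0, 1.0, FALSE)
  expect_lt(res$f, (0.25 - 1)^2)
  expect_gt(res$x, child)
  # non-improving child is a no-op by the precondition gate
  ev2 <- make_evaluator(function(x) (x - 1)^2, 0, 1.0, FALSE)
  res2 <- go_beyond(0.25, 0.6, 0.5, ev2, 0, 1.0, FALSE)
  # step towards lower x worsens: first trial rejected, child kept
  expect_identical(res2$x, 0.25)
  # steps are clipped at the bound and terminate
  ev3 <- make_evaluator(function(x) -x, 0, 1.0, FALSE)
  res3 <- go_beyond(0.9, -0.9, 0.1, ev3, 0, 1.0, FALSE)
  expect_identical(res3$x, 1.0)
})

test_that("mixed local refinement reaches the joint optimum and never worsens", {
  # quadratic with a binary switch: optimum (0.3, 1)
  fn <- function(x) (x[1] - 0.3)^2 + (x[2] - 1)^2
  lb <- c(0, 0); ub <- c(1, 1); im <- c(FALSE, TRUE)
  ev <- make_evaluator(fn, lb, ub, im)
  res <- local_refine_mixed(c(0.9, 0), ev, lb, ub, im, budget = 300)
  expect_lt(res$f, 1e-6)
  expect_equal(res$x[1], 0.3, tolerance = 1e-3)
  expect_identical(res$x[2], 1)
  # already at the optimum of a pure continuous quadratic: no worsening
  ev2 <- make_evaluator(function(x) sum((x - 0.5)^2), c(0, 0), c(1, 1),
                        c(FALSE, FALSE))
  res2 <- local_refine_mixed(c(0.5, 0.5), ev2, c(0, 0), c(1, 1),
                             c(FALSE, FALSE), budget = 200)
  expect_lte(res2$f, 1e-12)
  # pure-integer linear objective: 1-flip descent finds the enumerated optimum
  w <- c(0.7, -1.2, 0.4)
  fn3 <- function(b) sum(w * b)
  lb3 <- rep(0, 3); ub3 <- rep(1, 3); im3 <- rep(TRUE, 3)
  patterns <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  fstar <- min(apply(patterns, 1, fn3))
  ev3 <- make_evaluator(fn3, lb3, ub3, im3)
  res3 <- local_refine_mixed(c(1, 0, 1), ev3, lb3, ub3, im3, budget = 100)
  expect_identical(res3$f, fstar)
})

test_that("the evaluation audit rejects bound or integrality violations and counts calls", {
  ev <- make_evaluator(function(x) sum(x), c(0, 0), c(1, 1),
                       c(FALSE, TRUE))
  ev(c(0.5, 1)); ev(c(0.2, 0))
  expect_identical(eval_count(ev), 2L)
  expect_error(ev(c(1.5, 0)), "outside bounds")
  expect_error(ev(c(0.5, 0.5)), "fractional")
  expect_identical(eval_count(ev), 2L)  # refused calls are not counted
})

test_that("RefSet update inserts improvers, rejects near-duplicates and retires stale members", {
  set.seed(44)
  lb <- c(0, 0); ub <- c(1, 1); im <- c(FALSE, FALSE)
  ev <- make_evaluator(function(x) sum(x^2), lb, ub, im)
  s <- ess_settings(dim_refset = 4, max_age = 2)
  X <- matrix(c(0.2, 0.2, 0.4, 0.4, 0.6, 0.6, 0.9, 0.9), 4, 2,
              byrow = TRUE)
  f <- apply(X, 1, ev)
  rs <- list(X = X, f = f, age = rep(0L, 4))
  # candidate worse than all members leaves the RefSet unchanged
  up <- refset_update(rs, matrix(c(1, 1), 1), ev(c(1, 1)),
                      matrix(numeric(0), 0, 2), lb, ub, im, ev, s)
  expect_identical(up$refset$X[, 1], X[, 1])
  # an improving candidate replaces the worst member, order restored
  up2 <- refset_update(rs, matrix(c(0.1, 0.1), 1), ev(c(0.1, 0.1)),
                       matrix(numeric(0), 0, 2), lb, ub, im, ev, s)
  expect_identical(up2$refset$X[1, ], c(0.1, 0.1))
  expect_false(any(apply(up2$refset$X, 1, identical, c(0.9, 0.9))))
  expect_identical(up2$refset$f, sort(up2$refset$f))
  # near-duplicate of an existing member is rejected even when improving
  dup <- rs$X[1, ] + 1e-6
  up3 <- refset_update(rs, matrix(dup, 1), ev(dup) - 1,
                       matrix(numeric(0), 0, 2), lb, ub, im, ev, s)
  expect_false(any(apply(up3$refset$X, 1, function(r)
    all(abs(r - dup) < 1e-9))))
})

test_that("eSS solves the certified MINLP fixtures and logs a monotone trace", {
  fx <- minlp_fixtures()
  for (f in fx) {
    cert <- certify_minlp(f)
    expect_equal(cert$fstar, f$fstar, tolerance = 1e-8)
    res <- ess_run(f$fn, f$lb, f$ub, f$int_mask, max_evals = 20000,
                   vtr = f$fstar + 1e-8, seed = 7)
    expect_lt(res$f, f$fstar + 1e-6)
    expect_true(all(diff(res$log$fbest) <= 0))
  }
})

test_that("eSS stops immediately when the value-to-reach is trivially satisfied", {
  res <- ess_run(function(x) sum(x^2), rep(-1, 2), rep(1, 2),
                 vtr = 10, seed = 1)
  expect_identical(res$stopped_by, "vtr")
  expect_identical(res$iter, 0L)
})

test_that("fixed seed and settings reproduce the run, and eval counts are conserved", {
  f <- minlp_fixtures()[[1]]
  counted <- local({
    n <- 0L
    function(x) { n <<- n + 1L; f$fn(x) }
  })
  r1 <- ess_run(counted, f$lb, f$ub, f$int_mask, max_evals = 2000,
                seed = 11)
  actual_calls <- environment(counted)$n
  expect_identical(r1$neval, actual_calls)
  r2 <- ess_run(f$fn, f$lb, f$ub, f$int_mask, max_evals = 2000, seed = 11)
  expect_identical(r1$f, r2$f)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$log$neval, r2$log$neval)
  expect_identical(r1$log$fbest, r2$log$fbest)
  # convergence CSV round-trip
  path <- tempfile(fileext = ".csv")
  write_convergence_csv(r1, path)
  back <- read.csv(path)
  expect_named(back, c("neval", "wall_seconds", "fbest"))
})
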