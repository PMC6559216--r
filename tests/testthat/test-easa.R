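# Cheap synthetic evaluators for optimizer tests.
const_eval <- function(y = 5) function(tr) list(mean_yield = y, cv_yield = 1,
                                                mean_hi = 0.5)
# concave test objective scaled to yield-like magnitude (t/ha)
quad_eval <- function(center, width) function(tr)
  list(mean_yield = -100 * sum(((tr - center) / width)^2), cv_yield = 0,
       mean_hi = 0.5)

test_that("mutation respects bounds and inherits evolved steps", {
  spec <- optimization_spec()
  rg <- spec$ranges
  parent <- wheatideo:::new_candidate(
    setNames((rg$lower + rg$upper) / 2, rg$trait),
    0.1 * (rg$upper - rg$lower))
  set.seed(1)
  for (i in 1:20000) {
    off <- mutate_candidate(parent, spec)
    v <- off$values
    if (any(v < rg$lower - 1e-12) || any(v > rg$upper + 1e-12))
      fail("offspring left the trait ranges")
    if (any(off$steps < 1e-3 * (rg$upper - rg$lower) - 1e-15) ||
        any(off$steps > 0.5 * (rg$upper - rg$lower) + 1e-15))
      fail("step sizes left their clamp")
  }
  succeed()
})

test_that("mutation spread matches a Monte-Carlo oracle of the same rule", {
  spec <- optimization_spec()
  rg <- spec$ranges
  width <- rg$upper - rg$lower
  parent <- wheatideo:::new_candidate(
    setNames((rg$lower + rg$upper) / 2, rg$trait), 0.05 * width)
  set.seed(2)
  n <- 20000
  vals <- t(vapply(seq_len(n), function(i) mutate_candidate(parent, spec)$values,
                   numeric(8)))
  # independent oracle: re-draw the rule directly
  set.seed(3)
  tau <- 1 / sqrt(16)
  oracle <- sapply(1:8, function(j) {
    st <- pmin(0.5 * width[j], pmax(1e-3 * width[j],
                                    0.05 * width[j] * exp(tau * rnorm(n))))
    x <- pmin(rg$upper[j], pmax(rg$lower[j],
                                parent$values[j] + st * rnorm(n)))
    sd(x)
  })
  got <- apply(vals, 2, sd)
  expect_true(all(abs(got - oracle) / oracle < 0.10))
})

test_that("feasibility filter enforces the CV and HI ceilings", {
  spec <- optimization_spec()
  cand <- wheatideo:::new_candidate(traits_from_cultivar(cultivar_claire()),
                                    rep(1, 8))
  ev <- function(y, cv, hi) function(tr)
    list(mean_yield = y, cv_yield = cv, mean_hi = hi)
  expect_false(evaluate_candidate(cand, ev(10, 12, 0.5), spec)$feasible)
  expect_true(evaluate_candidate(cand, ev(10, 9, 0.64), spec)$feasible)
  expect_true(evaluate_candidate(cand, ev(10, 0, 0.5), spec)$feasible)
  expect_false(evaluate_candidate(cand, ev(10, 5, 0.65), spec)$feasible)
  # evaluator failure marks infeasible instead of aborting
  boom <- function(tr) stop("model blew up")
  expect_false(evaluate_candidate(cand, boom, spec)$feasible)
})

test_that("an elitist step retains the parent under a constant objective", {
  spec <- optimization_spec(offspring = 16)
  ev <- const_eval()
  parent <- evaluate_candidate(
    wheatideo:::new_candidate(traits_from_cultivar(cultivar_claire()),
                              rep(0.1, 8) * (spec$ranges$upper - spec$ranges$lower)),
    ev, spec)
  set.seed(5)
  out <- easa_step(parent, ev, spec)
  expect_equal(nrow(out$evaluations), 16)
  expect_equal(out$parent$mean_yield, parent$mean_yield)
})

test_that("the search recovers a known separable optimum within 1% of range", {
  spec <- optimization_spec(starts = 2, max_steps = 200, patience = 30)
  rg <- spec$ranges
  center <- setNames((rg$lower + rg$upper) / 2, rg$trait)
  r <- run_easa(spec, quad_eval(center, rg$upper - rg$lower), seed = 9)
  expect_false(is.null(r$best))
  err <- abs(r$best$values - center) / (rg$upper - rg$lower)
  expect_true(all(err < 0.01))
})

test_that("a monotone objective drives the trait to its bound", {
  spec <- optimization_spec(starts = 1, max_steps = 120, patience = 25)
  ev <- function(tr) list(mean_yield = tr[["P_h"]], cv_yield = 0,
                          mean_hi = 0.5)
  r <- run_easa(spec, ev, seed = 10)
  expect_gte(r$best$values[["P_h"]], 119)
})

test_that("trajectories are monotone non-decreasing and runs reproducible", {
  spec <- optimization_spec(starts = 2, max_steps = 40, patience = 40)
  rg <- spec$ranges
  center <- setNames(rg$lower + 0.3 * (rg$upper - rg$lower), rg$trait)
  ev <- quad_eval(center, rg$upper - rg$lower)
  r1 <- run_easa(spec, ev, seed = 11)
  r2 <- run_easa(spec, ev, seed = 11)
  expect_identical(r1$best$values, r2$best$values)
  for (s in unique(r1$trajectory$start)) {
    y <- r1$trajectory$mean_yield[r1$trajectory$start == s &
                                    r1$trajectory$feasible]
    expect_true(all(diff(y) >= -1e-12))
  }
})
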