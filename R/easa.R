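#' Optimization specification for ideotype design
#'
#' Search settings for the evolutionary search with self-adaptation:
#' the eight optimizable traits with their bounds, the number of offspring
#' per step (16), the number of independent starts (8; one fixed at the
#' base cultivar, the rest scattered uniformly), the feasibility ceilings
#' (yield CV <= 10\%, ensemble-mean HI <= 0.64), and the convergence rule
#' (stop when the best mean yield has not improved by more than `tol`
#' t ha-1 for `patience` consecutive steps, or after `max_steps`).
#'
#' @param ranges data.frame with columns `trait`, `lower`, `upper`.
#' @param offspring candidates generated per step.
#' @param starts independent optimization starts.
#' @param cv_max yield CV ceiling (\%).
#' @param hi_max ensemble-mean harvest index ceiling.
#' @param patience steps without improvement before stopping.
#' @param max_steps hard step limit per start.
#' @param tol minimum yield improvement counted as progress (t ha-1).
#' @param init_step_frac initial mutation step size as a fraction of each
#'   range width.
#' @param base_cultivar cultivar supplying the fixed start and the 14
#'   non-optimized parameters.
#' @return list of class `optimization_spec`.
#' @export
optimization_spec <- function(ranges = trait_ranges(), offspring = 16,
                              starts = 8, cv_max = 10, hi_max = 0.64,
                              patience = 20, max_steps = 200, tol = 1e-3,
                              init_step_frac = 0.1,
                              base_cultivar = cultivar_claire()) {
  stopifnot(all(c("trait", "lower", "upper") %in% names(ranges)),
            all(ranges$upper > ranges$lower), offspring >= 1, starts >= 1,
            cv_max > 0, hi_max > 0, patience >= 1, max_steps >= 1)
  structure(list(ranges = ranges, offspring = as.integer(offspring),
                 starts = as.integer(starts), cv_max = cv_max,
                 hi_max = hi_max, patience = as.integer(patience),
                 max_steps = as.integer(max_steps), tol = tol,
                 init_step_frac = init_step_frac,
                 base_cultivar = base_cultivar),
            class = "optimization_spec")
}

new_candidate <- function(values, steps) {
  list(values = values, steps = steps, mean_yield = NA_real_,
       cv = NA_real_, hi = NA_real_, feasible = NA, evaluated = FALSE)
}

#' Mutate a candidate with self-adaptive step sizes
#'
#' Log-normal self-adaptation: each per-coordinate step size is multiplied
#' by `exp(tau * N(0,1))` with `tau = 1/sqrt(2 * n)` (n = 8 traits) and
#' clamped to `[1e-3, 0.5]` of the range width; the trait value is then
#' perturbed by `step * N(0,1)` and clamped to its bounds. The offspring
#' inherits the evolved steps.
#'
#' @param parent candidate (list with `values`, `steps`).
#' @param spec an `optimization_spec`.
#' @return unevaluated offspring candidate.
#' @export
mutate_candidate <- function(parent, spec) {
  rg <- spec$ranges
  width <- rg$upper - rg$lower
  n <- nrow(rg)
  tau <- 1 / sqrt(2 * n)
  steps <- parent$steps * exp(tau * rnorm(n))
  steps <- pmin(0.5 * width, pmax(1e-3 * width, steps))
  values <- parent$values + steps * rnorm(n)
  values <- pmin(rg$upper, pmax(rg$lower, values))
  names(values) <- rg$trait
  new_candidate(values, steps)
}

#' Evaluate a candidate and apply the feasibility filter
#'
#' Feasible iff yield CV <= `cv_max` and ensemble-mean HI <= `hi_max`
#' (both ceilings inclusive). An evaluator failure marks the candidate
#' infeasible rather than aborting the search.
#'
#' @param candidate candidate to evaluate.
#' @param evaluator function taking the named 8-trait vector and returning
#'   a list with `mean_yield`, `cv_yield` (\%), `mean_hi` (an
#'   `ensemble_result` works directly).
#' @param spec an `optimization_spec`.
#' @return the candidate with `mean_yield`, `cv`, `hi`, `feasible` filled.
#' @export
evaluate_candidate <- function(candidate, evaluator, spec) {
  ev <- tryCatch(evaluator(candidate$values), error = function(e) NULL)
  if (is.null(ev)) {
    candidate$mean_yield <- -Inf
    candidate$cv <- Inf; candidate$hi <- Inf
    candidate$feasible <- FALSE
  } else {
    candidate$mean_yield <- ev$mean_yield
    candidate$cv <- ev$cv_yield
    candidate$hi <- ev$mean_hi
    candidate$feasible <- is.finite(ev$mean_yield) &&
      ev$cv_yield <= spec$cv_max && ev$mean_hi <= spec$hi_max
  }
  candidate$evaluated <- TRUE
  candidate
}

#' One elitist step of the evolutionary search
#'
#' Generates `spec$offspring` mutants of the parent, evaluates them, and
#' selects the next parent as the feasible candidate with the highest mean
#' yield among offspring plus the incumbent parent. If no feasible
#' candidate exists the parent is retained. When a generation yields no
#' improvement the incumbent's step sizes are contracted (factor 0.9,
#' clamped at the lower step bound), the elitist counterpart of success-
#' rule step control: without it the incumbent's steps never adapt on
#' failed generations and the search stagnates short of the optimum.
#'
#' @param parent evaluated candidate.
#' @inheritParams evaluate_candidate
#' @return list with `parent` (next parent) and `evaluations` (data.frame
#'   of all offspring records).
#' @export
easa_step <- function(parent, evaluator, spec) {
  off <- lapply(seq_len(spec$offspring), function(i)
    evaluate_candidate(mutate_candidate(parent, spec), evaluator, spec))
  pool <- c(list(parent), off)
  feas <- Filter(function(c) isTRUE(c$feasible), pool)
  nxt <- if (length(feas)) {
    yy <- vapply(feas, function(c) c$mean_yield, numeric(1))
    feas[[which.max(yy)]]
  } else parent
  if (identical(nxt$values, parent$values)) {
    width <- spec$ranges$upper - spec$ranges$lower
    nxt$steps <- pmax(1e-3 * width, 0.9 * nxt$steps)
  }
  rec <- do.call(rbind, lapply(off, function(c)
    data.frame(t(c$values), mean_yield = c$mean_yield, cv = c$cv,
               hi = c$hi, feasible = c$feasible)))
  list(parent = nxt, evaluations = rec)
}

#' Run the evolutionary search with self-adaptation
#'
#' Multi-start search over the 8-trait space. Start 1 is the base cultivar
#' (Claire); the remaining starts are uniform draws within the bounds.
#' Each start runs elitist steps until the best feasible mean yield has
#' not improved by more than `spec$tol` for `spec$patience` steps, or
#' `spec$max_steps` is reached. The overall best feasible candidate across
#' starts is returned.
#'
#' @param spec an `optimization_spec`.
#' @param evaluator see [evaluate_candidate()]. All candidates are scored
#'   against the same fixed weather realization (common random numbers),
#'   so the objective is deterministic.
#' @param seed integer seed for the search's own randomness.
#' @return list of class `easa_result`: `best` (overall best feasible
#'   candidate or NULL), `best_per_start`, `trajectory` (data.frame: start,
#'   step, parent mean yield), `evaluations` (every candidate scored, with
#'   feasibility), `converged_steps` per start.
#' @export
run_easa <- function(spec, evaluator, seed) {
  stopifnot(inherits(spec, "optimization_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rg <- spec$ranges
  width <- rg$upper - rg$lower
  init_steps <- spec$init_step_frac * width

  starts <- vector("list", spec$starts)
  starts[[1]] <- traits_from_cultivar(spec$base_cultivar)
  if (spec$starts > 1)
    for (s in 2:spec$starts)
      starts[[s]] <- setNames(rg$lower + runif(nrow(rg)) * width, rg$trait)

  best_per_start <- vector("list", spec$starts)
  traj <- list(); evals <- list(); steps_used <- integer(spec$starts)

  for (s in seq_len(spec$starts)) {
    parent <- evaluate_candidate(new_candidate(starts[[s]], init_steps),
                                 evaluator, spec)
    evals[[length(evals) + 1L]] <- data.frame(start = s, step = 0L,
      t(parent$values), mean_yield = parent$mean_yield, cv = parent$cv,
      hi = parent$hi, feasible = parent$feasible)
    best_y <- if (isTRUE(parent$feasible)) parent$mean_yield else -Inf
    stall <- 0L
    for (st in seq_len(spec$max_steps)) {
      out <- easa_step(parent, evaluator, spec)
      parent <- out$parent
      evals[[length(evals) + 1L]] <- cbind(start = s, step = st,
                                           out$evaluations)
      traj[[length(traj) + 1L]] <- data.frame(
        start = s, step = st, mean_yield = parent$mean_yield,
        feasible = isTRUE(parent$feasible))
      cur <- if (isTRUE(parent$feasible)) parent$mean_yield else -Inf
      if (cur > best_y + spec$tol) { best_y <- cur; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= spec$patience) break
    }
    steps_used[s] <- st
    best_per_start[[s]] <- parent
  }

  feas <- Filter(function(c) isTRUE(c$feasible), best_per_start)
  best <- if (length(feas)) {
    yy <- vapply(feas, function(c) c$mean_yield, numeric(1))
    feas[[which.max(yy)]]
  } else NULL

  structure(list(best = best, best_per_start = best_per_start,
                 trajectory = do.call(rbind, traj),
                 evaluations = do.call(rbind, evals),
                 converged_steps = steps_used, seed = seed),
            class = "easa_result")
}

#' Build a yield evaluator for a site, scenario and water mode
#'
#' Generates one fixed weather realization (common random numbers) and
#' returns a closure mapping an 8-trait vector to the ensemble statistics
#' of the corresponding cultivar.
#'
#' @param site a `site_climate` (already scenario-morphed if needed).
#' @param config a `sim_config`; its `lue` should carry any scenario
#'   light-use-efficiency multiplier.
#' @param n_seasons ensemble size (sowing years).
#' @param weather_seed seed for the shared weather realization.
#' @param base_cultivar template for the non-optimized parameters.
#' @return function(traits) -> `ensemble_result`.
#' @export
make_yield_evaluator <- function(site, config, n_seasons = 30,
                                 weather_seed = 1,
                                 base_cultivar = cultivar_claire()) {
  weather <- generate_weather(site, n_years = n_seasons + 1L,
                              seed = weather_seed)
  function(traits) {
    cv <- cultivar_from_traits(traits, base = base_cultivar)
    simulate_ensemble(cv, weather, config)
  }
}
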