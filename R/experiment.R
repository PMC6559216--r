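#' Percent difference relative to a baseline
#'
#' @param a quantity of interest.
#' @param b baseline (non-zero).
#' @param round_int round to integer percent (report convention).
#' @return `100 * (a - b) / b`.
#' @export
#' @examples
#' percent_difference(13.2, 10.8)  # 22 (%)
percent_difference <- function(a, b, round_int = TRUE) {
  if (any(b == 0)) stop("zero baseline in percent difference")
  p <- 100 * (a - b) / b
  if (round_int) round(p) else p
}

site_sim_config <- function(site_id, water_mode, lue = 1, ...) {
  i <- match(site_id, STUDY_SITES$site)
  if (is.na(i)) stop("unknown site id: ", site_id)
  uk <- STUDY_SITES$country[i] == "UK"
  sim_config(sowing_doy = if (uk) 293L else 110L,
             latitude = STUDY_SITES$latitude[i],
             soil = if (uk) "rothamsted_210" else "lincoln_270",
             water_mode = water_mode, lue = lue, ...)
}

#' Experiment configuration
#'
#' Describes a full ideotype-design experiment: the sites, ensemble size,
#' optimizer settings and seeds for the four treatments — the reference
#' cultivar under baseline climate (`CL_Base`) and under the 2050 scenario
#' (`CL_2050`), and ideotypes optimized under the 2050 scenario with a
#' 1.10 light-use-efficiency multiplier in rainfed (`IW_2050`) and
#' irrigated (`IP_2050`) conditions.
#'
#' @param sites character vector of built-in site ids.
#' @param n_seasons ensemble size (sowing years per treatment).
#' @param easa_starts,easa_steps optimizer starts and step cap.
#' @param weather_seed,easa_seed seeds.
#' @param treatments subset of `c("CL_Base","CL_2050","IW_2050","IP_2050")`.
#' @param lue_ideotype light-use-efficiency multiplier for the ideotype
#'   treatments.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(sites = c("ED", "LE", "RR", "GO", "LI", "PU"),
                              n_seasons = 100, easa_starts = 8,
                              easa_steps = 200, weather_seed = 1,
                              easa_seed = 1,
                              treatments = c("CL_Base", "CL_2050",
                                             "IW_2050", "IP_2050"),
                              lue_ideotype = 1.10) {
  bad <- setdiff(sites, STUDY_SITES$site)
  if (length(bad)) stop("unknown site(s): ", paste(bad, collapse = ", "))
  treatments <- match.arg(treatments, several.ok = TRUE)
  structure(list(sites = sites, n_seasons = as.integer(n_seasons),
                 easa_starts = as.integer(easa_starts),
                 easa_steps = as.integer(easa_steps),
                 weather_seed = as.integer(weather_seed),
                 easa_seed = as.integer(easa_seed),
                 treatments = treatments, lue_ideotype = lue_ideotype),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#' @param path file path.
#' @param config an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the ideotype-design experiment
#'
#' For each site: ensembles of the reference cultivar under baseline and
#' 2050 climate, and (if requested) evolutionary ideotype optimization
#' under the 2050 scenario in rainfed and irrigated mode. Deterministic
#' for fixed seeds.
#'
#' @param config an `experiment_config`.
#' @param out_dir optional directory; per-season CSVs, the ideotype table
#'   and a JSON summary are written there.
#' @return list of class `experiment_result` keyed by site, each holding
#'   the treatment `ensemble_result`s and `easa_result`s.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  res <- list()
  for (sid in config$sites) {
    i <- match(sid, STUDY_SITES$site)
    country <- STUDY_SITES$country[i]
    base_site <- builtin_site(sid)
    site_2050 <- apply_scenario(base_site, scenario_2050(country))
    site_res <- list(site = sid, country = country)

    if ("CL_Base" %in% config$treatments) {
      cfg <- site_sim_config(sid, "rainfed")
      ws <- generate_weather(base_site, config$n_seasons + 1L,
                             seed = config$weather_seed)
      site_res$CL_Base <- simulate_ensemble(cultivar_claire(), ws, cfg)
    }
    if ("CL_2050" %in% config$treatments) {
      cfg <- site_sim_config(sid, "rainfed")
      ws <- generate_weather(site_2050, config$n_seasons + 1L,
                             seed = config$weather_seed)
      site_res$CL_2050 <- simulate_ensemble(cultivar_claire(), ws, cfg)
    }
    spec <- optimization_spec(starts = config$easa_starts,
                              max_steps = config$easa_steps)
    if ("IW_2050" %in% config$treatments) {
      cfg <- site_sim_config(sid, "rainfed", lue = config$lue_ideotype)
      ev <- make_yield_evaluator(site_2050, cfg,
                                 n_seasons = config$n_seasons,
                                 weather_seed = config$weather_seed)
      site_res$IW_2050 <- run_easa(spec, ev, seed = config$easa_seed)
    }
    if ("IP_2050" %in% config$treatments) {
      cfg <- site_sim_config(sid, "irrigated", lue = config$lue_ideotype)
      ev <- make_yield_evaluator(site_2050, cfg,
                                 n_seasons = config$n_seasons,
                                 weather_seed = config$weather_seed)
      site_res$IP_2050 <- run_easa(spec, ev, seed = config$easa_seed)
    }
    res[[sid]] <- site_res
  }
  out <- structure(list(sites = res, config = config,
                        config_hash = config_hash(config)),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_experiment_outputs(out, out_dir)
  out
}

write_experiment_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(result$sites)) {
    sr <- result$sites[[sid]]
    for (tr in intersect(c("CL_Base", "CL_2050"), names(sr)))
      write.csv(sr[[tr]]$seasons,
                file.path(out_dir, paste0(sid, "_", tr, "_seasons.csv")),
                row.names = FALSE)
    for (tr in intersect(c("IW_2050", "IP_2050"), names(sr)))
      write.csv(sr[[tr]]$trajectory,
                file.path(out_dir, paste0(sid, "_", tr, "_trajectory.csv")),
                row.names = FALSE)
  }
  ideo <- ideotype_table(result)
  if (nrow(ideo))
    write.csv(ideo, file.path(out_dir, "ideotypes.csv"), row.names = FALSE)
  rep <- make_report(result)
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         weather_seed = result$config$weather_seed,
         easa_seed = result$config$easa_seed,
         summary = rep$site_means),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

# Optimized trait table: one row per site x water condition.
ideotype_table <- function(result) {
  rows <- list()
  for (sid in names(result$sites)) {
    sr <- result$sites[[sid]]
    for (tr in intersect(c("IW_2050", "IP_2050"), names(sr))) {
      b <- sr[[tr]]$best
      if (is.null(b)) next
      rows[[length(rows) + 1L]] <-
        data.frame(site = sid, country = sr$country, treatment = tr,
                   t(b$values), mean_yield = b$mean_yield,
                   cv = b$cv, hi = b$hi)
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

#' Report tables from an experiment result
#'
#' Site-level and country-level means (countries are unweighted means of
#' their three sites), percent gains of each treatment over the reference
#' cultivar under baseline climate, yield percentile tables and mean
#' phenology dates. Report rounding: percent gains to integer, yields to
#' 0.1 t ha-1.
#'
#' @param result an `experiment_result`.
#' @return list of data.frames: `site_means`, `country_means`,
#'   `percent_gains`, `yield_percentiles`, `phenology`, `ideotypes`.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (!length(result$sites)) stop("no data: empty experiment result")
  rows <- list(); pcts <- list(); phen <- list()
  for (sid in names(result$sites)) {
    sr <- result$sites[[sid]]
    for (tr in intersect(c("CL_Base", "CL_2050", "IW_2050", "IP_2050"),
                         names(sr))) {
      obj <- sr[[tr]]
      if (inherits(obj, "easa_result")) {
        if (is.null(obj$best)) next
        my <- obj$best$mean_yield; hi <- obj$best$hi; cv <- obj$best$cv
        pq <- NULL; a_das <- NA; m_das <- NA
      } else {
        my <- obj$mean_yield; hi <- obj$mean_hi; cv <- obj$cv_yield
        pq <- obj$yield_percentiles
        a_das <- obj$mean_anthesis_das; m_das <- obj$mean_maturity_das
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = sid, country = sr$country, treatment = tr,
        mean_yield = round(my, 1), cv = round(cv, 1), hi = round(hi, 2))
      if (!is.null(pq))
        pcts[[length(pcts) + 1L]] <- data.frame(
          site = sid, treatment = tr, t(round(pq, 1)))
      phen[[length(phen) + 1L]] <- data.frame(
        site = sid, treatment = tr, anthesis_das = round(a_das),
        maturity_das = round(m_das))
    }
  }
  site_means <- do.call(rbind, rows)
  agg <- stats::aggregate(mean_yield ~ country + treatment, site_means, mean)
  agg$mean_yield <- round(agg$mean_yield, 1)
  gains <- NULL
  if ("CL_Base" %in% site_means$treatment) {
    base <- site_means[site_means$treatment == "CL_Base",
                       c("site", "mean_yield")]
    names(base)[2] <- "base_yield"
    g <- merge(site_means[site_means$treatment != "CL_Base", ], base,
               by = "site")
    if (nrow(g))
      gains <- data.frame(g[, c("site", "treatment")],
                          gain_pct = percent_difference(g$mean_yield,
                                                        g$base_yield))
  }
  list(site_means = site_means, country_means = agg,
       percent_gains = gains,
       yield_percentiles = if (length(pcts)) do.call(rbind, pcts) else NULL,
       phenology = do.call(rbind, phen),
       ideotypes = ideotype_table(result))
}
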