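#' Treatment outcome metrics
#'
#' Computes the three study endpoints from a simulation: percentage
#' reduction of total tumor burden between the first and last sample,
#' the final resistant-cell fraction `(R1 + R2) / total * 100`, and the
#' composite efficacy score
#' `percent_reduction / (1 + resistance_fraction / 100)`, which discounts
#' tumor response by resistance development.
#'
#' @param result A converged `fotsim_result`.
#' @return Named list of class `fotsim_metrics`: `initial_burden`,
#'   `final_burden`, `percent_reduction`, `resistance_fraction`,
#'   `efficacy_score`.
#' @export
#' @examples
#' efficacy_score(32.76, 1.55)  # 32.26
outcome_metrics <- function(result) {
  if (isTRUE(result$is_dummy) || !isTRUE(result$converged)) {
    stop("outcome metrics require a converged simulation result")
  }
  burden <- total_tumor_burden(result$state)
  initial <- burden[1]
  final <- burden[length(burden)]
  if (initial <= 0) stop("undefined metrics: initial burden is zero")
  pr <- 100 * (1 - final / initial)
  last <- result$state[nrow(result$state), ]
  rf <- (last[["R1"]] + last[["R2"]]) / final * 100
  structure(list(
    initial_burden = initial, final_burden = final,
    percent_reduction = pr, resistance_fraction = rf,
    efficacy_score = pr / (1 + rf / 100)
  ), class = "fotsim_metrics")
}

#' @rdname outcome_metrics
#' @param percent_reduction,resistance_fraction Metric values (percent).
#' @export
efficacy_score <- function(percent_reduction, resistance_fraction) {
  percent_reduction / (1 + resistance_fraction / 100)
}

#' @export
print.fotsim_metrics <- function(x, ...) {
  cat(sprintf(paste0("tumor reduction: %.2f%% (burden %.2f -> %.2f)\n",
                     "resistance fraction: %.2f%%\nefficacy score: %.2f\n"),
              x$percent_reduction, x$initial_burden, x$final_burden,
              x$resistance_fraction, x$efficacy_score))
  invisible(x)
}

#' Comparative experiment grid design
#'
#' Enumerates the fractional-order x patient-profile x treatment-protocol
#' configurations of the comparative study. The default design crosses
#' the seven studied fractional orders with the four profiles and five
#' protocols: 140 configurations.
#'
#' @param alphas Fractional order values.
#' @param profiles Patient profile names.
#' @param protocols Treatment protocol names.
#' @return Data frame with columns `alpha`, `profile`, `protocol`.
#' @export
#' @examples
#' nrow(grid_design())  # 140
grid_design <- function(alphas = default_alphas(),
                        profiles = profile_names(),
                        protocols = protocol_names()) {
  g <- expand.grid(protocol = protocols, profile = profiles, alpha = alphas,
                   stringsAsFactors = FALSE)
  g <- g[, c("alpha", "profile", "protocol")]
  g <- g[order(g$alpha, match(g$profile, profiles),
               match(g$protocol, protocols)), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' @rdname grid_design
#' @export
default_alphas <- function() c(0.75, 0.80, 0.85, 0.90, 0.93, 0.95, 1.00)

#' Run the comparative experiment grid
#'
#' Runs one 500-day simulation per (alpha, profile, protocol)
#' configuration and collects the outcome metrics. Rows are ordered by
#' alpha, then profile, then protocol (in the order supplied).
#' Non-converged simulations are flagged in the `converged` column,
#' excluded from rankings, and counted in the attached convergence
#' report. Execution is deterministic regardless of `workers`.
#'
#' @param alphas,profiles,protocols Grid axes (see [grid_design()]).
#' @param config Base `fotsim_config`; its `alpha` is overridden per row.
#' @param baseline Baseline `fotsim_params` before profile application.
#' @param workers Parallel workers (forked via [parallel::mclapply()];
#'   1 = serial).
#' @return Data frame of class `fotsim_grid` with the design columns,
#'   the three metrics, burdens, and solver diagnostics; attribute
#'   `"convergence"` holds the run/converged counts.
#' @export
run_grid <- function(alphas = default_alphas(), profiles = profile_names(),
                     protocols = protocol_names(),
                     config = simulation_config(),
                     baseline = default_parameters(), workers = 1) {
  design <- grid_design(alphas, profiles, protocols)
  pcache <- lapply(stats::setNames(nm = unique(design$profile)),
                   function(pr) apply_profile(baseline, pr))
  run_one <- function(i) {
    row <- design[i, ]
    params <- pcache[[row$profile]]
    cfg <- config
    cfg$alpha <- row$alpha
    protocol <- treatment_protocol(row$protocol, params = params)
    res <- safe_solve(cfg, params, protocol)
    if (res$converged) {
      m <- outcome_metrics(res)
      data.frame(alpha = row$alpha, profile = row$profile,
                 protocol = row$protocol,
                 initial_burden = m$initial_burden,
                 final_burden = m$final_burden,
                 percent_reduction = m$percent_reduction,
                 resistance_fraction = m$resistance_fraction,
                 efficacy_score = m$efficacy_score,
                 converged = TRUE, method = res$method_used,
                 fallback_level = res$fallback_level,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(alpha = row$alpha, profile = row$profile,
                 protocol = row$protocol, initial_burden = NA_real_,
                 final_burden = NA_real_, percent_reduction = NA_real_,
                 resistance_fraction = NA_real_, efficacy_score = NA_real_,
                 converged = FALSE, method = NA_character_,
                 fallback_level = res$fallback_level,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(design)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(design)), run_one)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "convergence") <- list(
    n_runs = nrow(grid), n_converged = sum(grid$converged),
    retention = mean(grid$converged)
  )
  class(grid) <- c("fotsim_grid", class(grid))
  grid
}

grid_slice <- function(grid, alpha = NULL, profile = NULL, protocol = NULL) {
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(alpha)) keep <- keep & abs(grid$alpha - alpha) < 1e-9
  if (!is.null(profile)) keep <- keep & grid$profile == profile
  if (!is.null(protocol)) keep <- keep & grid$protocol == protocol
  out <- grid[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("requested grid slice is empty")
  out
}

#' Rank protocols by efficacy
#'
#' Orders the protocols of one grid slice by descending efficacy score;
#' ties are broken by higher percent reduction, then alphabetically by
#' protocol name. `profile = NULL` averages each protocol's metrics over
#' all profiles in the grid before ranking.
#'
#' @param grid A `fotsim_grid`.
#' @param alpha Fractional order of the slice.
#' @param profile Profile name, or `NULL` for the across-profile mean.
#' @return Data frame with `rank`, `protocol`, `efficacy_score`,
#'   `percent_reduction`, `resistance_fraction`.
#' @export
rank_protocols <- function(grid, alpha, profile = "average") {
  sl <- grid_slice(grid, alpha = alpha, profile = profile)
  sl <- sl[sl$converged, , drop = FALSE]
  if (nrow(sl) == 0) stop("no converged rows in the requested slice")
  if (is.null(profile)) {
    agg <- stats::aggregate(
      sl[, c("efficacy_score", "percent_reduction", "resistance_fraction")],
      by = list(protocol = sl$protocol), FUN = mean)
  } else {
    agg <- sl[, c("protocol", "efficacy_score", "percent_reduction",
                  "resistance_fraction")]
  }
  ord <- order(-agg$efficacy_score, -agg$percent_reduction, agg$protocol)
  agg <- agg[ord, , drop = FALSE]
  agg <- cbind(rank = seq_len(nrow(agg)), agg)
  rownames(agg) <- NULL
  agg
}

#' Optimal protocol for a profile and fractional order
#'
#' The argmax of the efficacy score over protocols in the requested
#' slice (the first row of [rank_protocols()]).
#'
#' @inheritParams rank_protocols
#' @return One-row data frame with `protocol` and `efficacy_score`.
#' @export
optimal_protocol <- function(grid, profile, alpha) {
  r <- rank_protocols(grid, alpha = alpha, profile = profile)
  r[1, c("protocol", "efficacy_score")]
}

#' Protocol variability across fractional orders
#'
#' For each protocol in one profile's slice, summarizes the efficacy
#' score across the fractional orders of the grid: min, max, range,
#' sample standard deviation and coefficient of variation
#' `100 * sd / mean`.
#'
#' @param grid A `fotsim_grid` covering at least two fractional orders.
#' @param profile Profile name.
#' @return Data frame, one row per protocol, ordered by decreasing range.
#' @export
protocol_variability <- function(grid, profile = "average") {
  sl <- grid_slice(grid, profile = profile)
  sl <- sl[sl$converged, , drop = FALSE]
  if (length(unique(sl$alpha)) < 2) {
    stop("variability requires at least two fractional-order values")
  }
  out <- do.call(rbind, lapply(split(sl, sl$protocol), function(d) {
    e <- d$efficacy_score
    data.frame(protocol = d$protocol[1], min_efficacy = min(e),
               max_efficacy = max(e), range = max(e) - min(e),
               sd = stats::sd(e), cv = 100 * stats::sd(e) / mean(e),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$range), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare fractional-order and integer-order predictions
#'
#' Pools all grid rows with `alpha < 1` ("fractional") against the
#' `alpha = 1` rows ("integer") and reports: aggregate mean +/- sd of
#' the three metrics with absolute and percent differences; per
#' patient-protocol context the integer efficacy, the pooled fractional
#' mean, and the best single fractional order (the alpha maximizing
#' efficacy in that context), each with percent difference
#' `100 * (fractional - integer) / integer`; and per-profile and
#' per-protocol means of the same comparison.
#'
#' @param grid A `fotsim_grid` containing `alpha = 1` and at least one
#'   `alpha < 1`.
#' @return List with `aggregate`, `by_context`, `by_profile`,
#'   `by_protocol` data frames.
#' @export
compare_fractional_integer <- function(grid) {
  g <- grid[grid$converged, , drop = FALSE]
  int <- g[abs(g$alpha - 1) < 1e-9, , drop = FALSE]
  frac <- g[g$alpha < 1 - 1e-9, , drop = FALSE]
  if (nrow(int) == 0) stop("grid has no integer-order (alpha = 1) rows")
  if (nrow(frac) == 0) stop("grid has no fractional-order (alpha < 1) rows")

  metrics <- c("percent_reduction", "resistance_fraction", "efficacy_score")
  aggregate_tbl <- do.call(rbind, lapply(metrics, function(m) {
    im <- mean(int[[m]]); fm <- mean(frac[[m]])
    data.frame(metric = m,
               integer_mean = im, integer_sd = stats::sd(int[[m]]),
               fractional_mean = fm, fractional_sd = stats::sd(frac[[m]]),
               difference = fm - im,
               difference_pct = 100 * (fm - im) / im,
               stringsAsFactors = FALSE)
  }))

  ctx <- unique(g[, c("profile", "protocol")])
  by_context <- do.call(rbind, lapply(seq_len(nrow(ctx)), function(i) {
    pr <- ctx$profile[i]; pt <- ctx$protocol[i]
    gi <- int[int$profile == pr & int$protocol == pt, , drop = FALSE]
    gf <- frac[frac$profile == pr & frac$protocol == pt, , drop = FALSE]
    if (nrow(gi) == 0 || nrow(gf) == 0) return(NULL)
    ie <- mean(gi$efficacy_score)
    fe <- mean(gf$efficacy_score)
    best <- gf[which.max(gf$efficacy_score), ]
    data.frame(profile = pr, protocol = pt,
               integer_efficacy = ie, fractional_efficacy = fe,
               difference_pct = 100 * (fe - ie) / ie,
               best_alpha = best$alpha,
               best_fractional_efficacy = best$efficacy_score,
               best_difference_pct = 100 * (best$efficacy_score - ie) / ie,
               stringsAsFactors = FALSE)
  }))
  rownames(by_context) <- NULL

  group_cmp <- function(col) {
    vals <- unique(g[[col]])
    out <- do.call(rbind, lapply(vals, function(v) {
      ie <- mean(int$efficacy_score[int[[col]] == v])
      fe <- mean(frac$efficacy_score[frac[[col]] == v])
      data.frame(group = v, integer_efficacy = ie, fractional_efficacy = fe,
                 difference_pct = 100 * (fe - ie) / ie,
                 stringsAsFactors = FALSE)
    }))
    names(out)[1] <- col
    out
  }
  list(aggregate = aggregate_tbl, by_context = by_context,
       by_profile = group_cmp("profile"), by_protocol = group_cmp("protocol"))
}

#' Local sensitivity-analysis design
#'
#' Enumerates the one-at-a-time perturbation design: every model
#' parameter (the fractional order is excluded) x every profile x
#' protocol context x the four multiplicative perturbation levels
#' (-20%, -10%, +10%, +20%). The full default design has
#' 58 x 20 x 4 = 4640 rows.
#'
#' @param parameters Parameter names to perturb.
#' @param profiles,protocols Context axes.
#' @param levels Relative perturbations (fractions).
#' @return Data frame with columns `parameter`, `profile`, `protocol`,
#'   `level`.
#' @export
#' @examples
#' nrow(sensitivity_design())  # 4640
sensitivity_design <- function(parameters = parameter_names(),
                               profiles = profile_names(),
                               protocols = protocol_names(),
                               levels = c(-0.20, -0.10, 0.10, 0.20)) {
  d <- expand.grid(level = levels, protocol = protocols, profile = profiles,
                   parameter = parameters, stringsAsFactors = FALSE)
  d <- d[, c("parameter", "profile", "protocol", "level")]
  rownames(d) <- NULL
  d
}

#' Normalized local sensitivity analysis
#'
#' One-at-a-time multiplicative perturbation of model parameters around
#' their (profile-adjusted) baseline values, across patient-profile x
#' treatment-protocol contexts. For each record the normalized
#' sensitivity coefficient is
#' `S = (delta_O / O_baseline) / (delta_p / p_baseline)`, computed for
#' each of the three outcome metrics. For each parameter the maximum
#' `|S|` over all levels and contexts (on `ranking_metric`) gives the
#' ranking, and parameters are classified as critical (`|S|max >= 1`),
#' important (`>= 0.5`) or non-critical. Records from non-converged
#' simulations are excluded and counted; the design requires more than
#' 95% retention.
#'
#' A custom `simulator` (signature
#' `function(params, profile, protocol, alpha)`, returning the named
#' metric vector) can be injected, e.g. to validate the engine against a
#' closed-form response.
#'
#' @param baseline Baseline `fotsim_params`.
#' @param parameters,profiles,protocols,levels Design axes (see
#'   [sensitivity_design()]).
#' @param alpha Fractional order used for all runs (default 1.0).
#' @param config Base `fotsim_config`.
#' @param ranking_metric Metric used for `S_max` ranking (default the
#'   efficacy score).
#' @param workers Parallel workers for the simulation runs.
#' @param simulator Optional injected outcome function.
#' @return List of class `fotsim_sensitivity`: `records` (one row per
#'   parameter x context x level x metric), `ranking` (per-parameter
#'   `s_max` with source category, functional group and class),
#'   `by_source` and `by_group` mean `s_max` aggregations, `retention`,
#'   and the attempted/converged run counts.
#' @export
sensitivity_analysis <- function(baseline = default_parameters(),
                                 parameters = parameter_names(),
                                 profiles = profile_names(),
                                 protocols = protocol_names(),
                                 levels = c(-0.20, -0.10, 0.10, 0.20),
                                 alpha = 1.0,
                                 config = simulation_config(alpha = alpha),
                                 ranking_metric = "efficacy_score",
                                 workers = 1, simulator = NULL) {
  config$alpha <- alpha
  if (is.null(simulator)) {
    simulator <- function(params, profile, protocol, alpha) {
      cfg <- config
      cfg$alpha <- alpha
      prot <- treatment_protocol(protocol, params = params)
      res <- safe_solve(cfg, params, prot)
      if (!res$converged) {
        return(c(percent_reduction = NA_real_,
                 resistance_fraction = NA_real_,
                 efficacy_score = NA_real_))
      }
      m <- outcome_metrics(res)
      c(percent_reduction = m$percent_reduction,
        resistance_fraction = m$resistance_fraction,
        efficacy_score = m$efficacy_score)
    }
  }
  metrics <- c("percent_reduction", "resistance_fraction", "efficacy_score")
  contexts <- expand.grid(protocol = protocols, profile = profiles,
                          stringsAsFactors = FALSE)[, c("profile", "protocol")]
  base_params <- lapply(stats::setNames(nm = unique(contexts$profile)),
                        function(pr) apply_profile(baseline, pr))
  base_out <- lapply(seq_len(nrow(contexts)), function(i) {
    simulator(base_params[[contexts$profile[i]]], contexts$profile[i],
              contexts$protocol[i], alpha)
  })

  design <- sensitivity_design(parameters, profiles, protocols, levels)
  run_one <- function(i) {
    row <- design[i, ]
    ci <- which(contexts$profile == row$profile &
                  contexts$protocol == row$protocol)
    O0 <- base_out[[ci]]
    p0 <- base_params[[row$profile]]
    pv <- p0[[row$parameter]] * (1 + row$level)
    pert <- p0
    pert[[row$parameter]] <- pv
    pert <- tryCatch(validate_parameters(pert), error = function(e) NULL)
    if (is.null(pert)) {
      return(data.frame(row, metric = metrics, S = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE,
                        row.names = NULL))
    }
    O1 <- simulator(pert, row$profile, row$protocol, alpha)
    conv <- all(is.finite(O1)) && all(is.finite(O0))
    S <- if (conv) {
      ifelse(abs(O0[metrics]) > 0,
             ((O1[metrics] - O0[metrics]) / O0[metrics]) / row$level,
             NA_real_)
    } else rep(NA_real_, length(metrics))
    data.frame(row, metric = metrics, S = as.numeric(S),
               converged = conv & is.finite(S), stringsAsFactors = FALSE,
               row.names = NULL)
  }
  chunks <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(design)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(design)), run_one)
  }
  records <- do.call(rbind, chunks)
  rownames(records) <- NULL
  cats <- parameter_categories(baseline)
  grps <- parameter_groups(baseline)
  records$source <- unname(cats[records$parameter])
  records$group <- unname(grps[records$parameter])

  rank_rec <- records[records$metric == ranking_metric & records$converged, ,
                      drop = FALSE]
  ranking <- do.call(rbind, lapply(unique(design$parameter), function(p) {
    r <- rank_rec[rank_rec$parameter == p, , drop = FALSE]
    s_max <- if (nrow(r) > 0) max(abs(r$S)) else NA_real_
    data.frame(parameter = p, source = unname(cats[p]), group = unname(grps[p]),
               s_max = s_max, stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$s_max), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  ranking$class <- classify_sensitivity(ranking$s_max)
  ranking <- ranking[, c("rank", "parameter", "source", "group", "s_max",
                         "class")]
  rownames(ranking) <- NULL

  by_source <- stats::aggregate(s_max ~ source, data = ranking, FUN = mean)
  by_group <- stats::aggregate(s_max ~ group, data = ranking, FUN = mean)
  n_runs <- nrow(design)
  per_run_conv <- records$converged[records$metric == ranking_metric]
  retention <- mean(per_run_conv)
  if (retention <= 0.95) {
    warning(sprintf("sensitivity retention %.1f%% is at or below 95%%",
                    100 * retention))
  }
  structure(list(records = records, ranking = ranking, by_source = by_source,
                 by_group = by_group, retention = retention,
                 n_runs = n_runs, n_converged = sum(per_run_conv),
                 alpha = alpha, ranking_metric = ranking_metric),
            class = "fotsim_sensitivity")
}

#' Classify maximum sensitivity coefficients
#'
#' `|S|max >= 1` is critical, `0.5 <= |S|max < 1` important, below 0.5
#' non-critical (boundary values classify upward).
#'
#' @param s_max Numeric vector of maximum absolute sensitivities.
#' @return Character vector.
#' @export
classify_sensitivity <- function(s_max) {
  ifelse(is.na(s_max), NA_character_,
         ifelse(s_max >= 1.0, "critical",
                ifelse(s_max >= 0.5, "important", "non-critical")))
}

#' @export
print.fotsim_sensitivity <- function(x, ...) {
  cat("<fotsim_sensitivity>", x$n_runs, "runs,",
      sprintf("retention %.1f%%", 100 * x$retention), "\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}
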