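# The validation workflow: null-model batteries, ANOVA/Tukey model
# comparisons, metric verdicts, and placement of empirical stands against
# the simulated null distributions.

#' The standard set of five null models
#'
#' @param kappa,mu,r_d,r_g,p Shared parameters passed to [null_model()].
#' @param ... Further arguments passed to every [null_model()] call
#'   (e.g. `kappa_is`, `n_mode`).
#' @return A named list of five `null_model` configurations.
#' @examples
#' names(default_null_models())
#' @export
default_null_models <- function(kappa = 0.015, mu = 3, r_d = 5, r_g = 4,
                                p = 0.5, ...) {
  models <- c("csr", "matern", "thomas", "hardcore", "strauss")
  setNames(
    lapply(models, function(m) {
      null_model(m, kappa = kappa, mu = mu, r_d = r_d, r_g = r_g, p = p, ...)
    }),
    models
  )
}

#' Ecological process group of each null model
#'
#' Cluster processes emulate dispersal limitation, Gibbs processes
#' competitive exclusion, and CSR the absence of structure. Metric verdicts
#' ask whether these three groups can be told apart.
#'
#' @return A named character vector mapping model name to group.
#' @export
model_groups <- function() {
  c(
    csr = "random", matern = "cluster", thomas = "cluster",
    hardcore = "gibbs", strauss = "gibbs"
  )
}

#' Run a Monte-Carlo null-model battery
#'
#' For each model and replicate: simulate a pattern, attach crown radii by
#' random labelling, build each requested network, and compute its
#' [network_metrics()]. Replicate `i` of every model uses seed `seed + i`,
#' so a battery is deterministic given its master seed and the models share
#' simulation randomness replicate-by-replicate (paired comparisons). A
#' replicate that fails (e.g. a non-converged Gibbs chain) is retried once
#' with a deterministic fallback seed, then dropped with a warning; dropped
#' replicates are recorded in the `"failed"` attribute.
#'
#' @param models A named list of [null_model()] configurations.
#' @param window Simulation window (default 200 m x 200 m).
#' @param crowns A crown distribution for random labelling.
#' @param net_types Networks to build per replicate.
#' @param n_sim Replicates per model (default 199).
#' @param seed Master seed (default 1).
#' @param d_max CS connection radius in metres.
#' @return A tibble with one row per (model, replicate, net_type):
#'   the [network_metrics()] columns plus `model` and `replicate`.
#' @examples
#' batch <- run_null_battery(
#'   default_null_models()[c("csr", "thomas")],
#'   n_sim = 2, seed = 1, net_types = "cs"
#' )
#' batch[, c("model", "replicate", "N", "E", "k")]
#' @export
run_null_battery <- function(models = default_null_models(),
                             window = plot_window(),
                             crowns = crown_uniform(2, 5),
                             net_types = c("cs", "cl", "wcl"),
                             n_sim = 199, seed = 1, d_max = 10) {
  if (n_sim < 2) abort("`n_sim` must be at least 2.")
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$model, character(1))
  }
  net_types <- match.arg(net_types, c("cs", "cl", "wcl"), several.ok = TRUE)
  window <- as_plot_window(window)
  failed <- list()
  rows <- vector("list", length(models) * n_sim)
  idx <- 0
  for (rep_i in seq_len(n_sim)) {
    for (m in names(models)) {
      idx <- idx + 1
      one <- function(rep_seed) {
        set.seed(rep_seed)
        pat <- simulate_pattern(models[[m]], window, seed = NULL)
        pat <- assign_crown_radii(pat, crowns)
        nets <- build_networks(pat, net_types, d_max = d_max)
        met <- dplyr::bind_rows(lapply(nets, network_metrics))
        met$model <- m
        met$replicate <- rep_i
        met
      }
      res <- tryCatch(one(seed + rep_i), error = function(e) e)
      if (inherits(res, "error")) {
        res <- tryCatch(one(seed + rep_i + 500000L), error = function(e) e)
      }
      if (inherits(res, "error")) {
        failed[[length(failed) + 1]] <- list(
          model = m, replicate = rep_i, message = conditionMessage(res)
        )
        rows[idx] <- list(NULL)
      } else {
        rows[[idx]] <- res
      }
    }
  }
  if (length(failed) > 0) {
    warn(sprintf("%d replicate(s) failed twice and were dropped.", length(failed)))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "model", "replicate")
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  attr(out, "failed") <- failed
  attr(out, "window") <- window
  out
}

battery_metric <- function(batch, metric, net_type = NULL) {
  if (!metric %in% names(batch)) {
    abort(sprintf("Metric `%s` is not a column of the battery.", metric))
  }
  if (!is.null(net_type)) {
    batch <- batch[batch$net_type %in% net_type, , drop = FALSE]
  } else if (length(unique(batch$net_type)) > 1) {
    abort("Battery holds several net types; supply `net_type`.")
  }
  tibble::tibble(
    model = batch$model,
    replicate = batch$replicate,
    value = batch[[metric]]
  )
}

#' Compare null models on one network metric
#'
#' One-way ANOVA of the metric across models, followed by Tukey's honest
#' significant differences over all model pairs, plus a pairwise
#' range-overlap matrix computed from each model's simulated minimum and
#' maximum. Significance and range separation are reported separately
#' because they answer different questions (mean shifts versus full
#' distributional separation).
#'
#' @param batch A [run_null_battery()] result.
#' @param metric Metric column name (`"k"`, `"C"`, `"D"`, `"L"`, `"E"`,
#'   `"k_weighted"`, ...).
#' @param net_type Which network type to compare (required when the battery
#'   holds several).
#' @param conf_level Tukey family-wise confidence level.
#' @return A `crownet_comparison` object; see [tidy.crownet_comparison()]
#'   and [glance.crownet_comparison()].
#' @examples
#' batch <- run_null_battery(
#'   default_null_models()[c("csr", "thomas")],
#'   n_sim = 5, seed = 1, net_types = "cs"
#' )
#' glance(compare_models(batch, "k", "cs"))
#' @export
compare_models <- function(batch, metric, net_type = NULL, conf_level = 0.95) {
  dat <- battery_metric(batch, metric, net_type)
  dat <- dat[is.finite(dat$value), , drop = FALSE]
  if (length(unique(dat$model)) < 2) {
    abort("Need at least 2 models to compare.")
  }
  dat$model <- factor(dat$model)
  fit <- aov(value ~ model, data = dat)
  anova_tbl <- summary(fit)[[1]]
  zero_resid <- anova_tbl["Residuals", "Sum Sq"] < .Machine$double.eps
  if (zero_resid) {
    warn("Zero within-model variance; ANOVA p-value is not meaningful.")
  }
  tk <- TukeyHSD(fit, conf.level = conf_level)$model
  pairs <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  ranges <- dplyr::summarise(
    dplyr::group_by(dat, .data$model),
    min = min(.data$value), max = max(.data$value),
    mean = mean(.data$value), .groups = "drop"
  )
  split_pair <- strsplit(pairs$pair, "-", fixed = TRUE)
  ov <- vapply(split_pair, function(p) {
    a <- ranges[ranges$model == p[1], ]
    b <- ranges[ranges$model == p[2], ]
    a$min <= b$max && b$min <= a$max
  }, logical(1))
  pairs$ranges_overlap <- ov
  structure(
    list(
      metric = metric,
      net_type = net_type %||% unique(batch$net_type),
      fit = fit,
      anova = anova_tbl,
      pairs = pairs,
      ranges = ranges,
      zero_residual = zero_resid
    ),
    class = "crownet_comparison"
  )
}

#' @export
print.crownet_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<crownet_comparison> metric %s on %s: F = %.3g, p = %.3g\n",
    x$metric, paste(x$net_type, collapse = "/"), g$statistic, g$p.value
  ))
  print(x$pairs)
  invisible(x)
}

#' Tidy a model comparison
#'
#' `tidy()` returns the Tukey pairwise table (mean difference, adjusted
#' p-value, and whether the two models' simulated ranges overlap);
#' `glance()` returns the one-row ANOVA summary.
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crownet_comparison <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.crownet_comparison
#' @export
glance.crownet_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    statistic = x$anova["model", "F value"],
    p.value = x$anova["model", "Pr(>F)"],
    df = x$anova["model", "Df"],
    df.residual = x$anova["Residuals", "Df"],
    n_models = nrow(x$ranges)
  )
}

#' Generics for tidy() and glance()
#'
#' Thin broom-style generics so comparison objects work with the usual
#' `tidy()`/`glance()` idiom without depending on broom.
#'
#' @param x An object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Is a metric able to distinguish the process groups?
#'
#' A metric is labelled *distinguishing* when every pair of models drawn
#' from different process groups (cluster, random, Gibbs; see
#' [model_groups()]) is significant under Tukey's test at `alpha` *and* has
#' non-overlapping simulated ranges. Both components are also reported
#' separately.
#'
#' @inheritParams compare_models
#' @param alpha Significance level for the Tukey criterion.
#' @param groups Named vector mapping model to process group.
#' @return A one-row tibble: `metric`, `net_type`, `distinguishing`,
#'   `n_pairs`, `n_significant`, `n_disjoint`.
#' @export
classify_metric <- function(batch, metric, net_type = NULL, alpha = 0.05,
                            groups = model_groups()) {
  cmp <- compare_models(batch, metric, net_type)
  sp <- strsplit(cmp$pairs$pair, "-", fixed = TRUE)
  cross <- vapply(sp, function(p) {
    ga <- groups[p[1]]
    gb <- groups[p[2]]
    !is.na(ga) && !is.na(gb) && ga != gb
  }, logical(1))
  if (!any(cross)) abort("No cross-group model pairs in this battery.")
  pp <- cmp$pairs[cross, , drop = FALSE]
  tibble::tibble(
    metric = metric,
    net_type = paste(cmp$net_type, collapse = "/"),
    distinguishing = all(pp$p_adj < alpha) && all(!pp$ranges_overlap),
    n_pairs = nrow(pp),
    n_significant = sum(pp$p_adj < alpha),
    n_disjoint = sum(!pp$ranges_overlap)
  )
}

#' @rdname classify_metric
#' @param metrics Metric columns to classify.
#' @export
classify_metrics <- function(batch, metrics = c("k", "C", "D", "L"),
                             net_type = NULL, alpha = 0.05,
                             groups = model_groups()) {
  dplyr::bind_rows(lapply(metrics, function(m) {
    classify_metric(batch, m, net_type, alpha, groups)
  }))
}

#' Place an empirical stand against the null distributions
#'
#' Runs the null-model battery with parameters matched to an observed stem
#' map -- intensity estimated from the tree density ([estimate_intensity()];
#' the cluster models use `kappa_is = "total"` so the simulated density
#' matches the stand) and crown radii drawn from a maximum-likelihood gamma
#' fit of the observed radii ([fit_crown_gamma()]) -- then locates each
#' observed network metric within each model's simulated distribution.
#'
#' @param trees An observed tree pattern with crown radii and a window
#'   (see [as_tree_pattern()] / [read_stem_map()]).
#' @param models Optional named list of null models; by default the five
#'   standard models at the estimated intensity.
#' @param net_types,n_sim,seed,d_max As in [run_null_battery()].
#' @param metrics Metric columns to compare.
#' @return A tibble with one row per (net_type, metric, model): the
#'   observed value, its percentile within the simulated distribution
#'   (0-100), and whether it falls inside the simulated min-max range.
#' @export
empirical_vs_null <- function(trees, models = NULL,
                              net_types = c("cs", "cl", "wcl"),
                              n_sim = 199, seed = 1, d_max = 10,
                              metrics = c("k", "C", "D", "L", "k_weighted")) {
  window <- pattern_window(trees)
  if (!"crown_radius" %in% names(trees)) {
    abort("`trees` needs a `crown_radius` column (see read_stem_map()).")
  }
  if (is.null(models)) {
    kappa_hat <- estimate_intensity(trees, window)
    models <- default_null_models(kappa = kappa_hat, kappa_is = "total")
  }
  crowns <- fit_crown_gamma(trees$crown_radius)
  batch <- run_null_battery(
    models, window, crowns, net_types,
    n_sim = n_sim, seed = seed, d_max = d_max
  )
  nets <- build_networks(trees, net_types, d_max = d_max)
  observed <- dplyr::bind_rows(lapply(nets, network_metrics))
  obs_long <- tidyr::pivot_longer(
    observed[, c("net_type", intersect(metrics, names(observed)))],
    -"net_type", names_to = "metric", values_to = "observed"
  )
  sim_long <- tidyr::pivot_longer(
    batch[, c("model", "net_type", intersect(metrics, names(batch)))],
    c(-"model", -"net_type"), names_to = "metric", values_to = "value"
  )
  sim_long <- sim_long[is.finite(sim_long$value), , drop = FALSE]
  out <- dplyr::inner_join(obs_long, sim_long, by = c("net_type", "metric"),
                           relationship = "one-to-many")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$net_type, .data$metric, .data$model),
    observed = .data$observed[1],
    percentile = 100 * mean(.data$value <= .data$observed[1]),
    in_range = .data$observed[1] >= min(.data$value) &
      .data$observed[1] <= max(.data$value),
    sim_mean = mean(.data$value),
    .groups = "drop"
  )
  out <- out[!is.na(out$observed), , drop = FALSE]
  attr(out, "batch") <- batch
  out
}

#' Parameter sensitivity sweep
#'
#' Re-runs the full battery for each value of one simulation parameter
#' (`kappa`, `r_d`, `r_g` or `mu`) and stacks the results with the
#' parameter value annotated, ready for faceted plotting of how every
#' metric responds.
#'
#' @param param Parameter to vary.
#' @param values Numeric vector of parameter values.
#' @param ... Arguments passed on to [default_null_models()] (other
#'   parameters) and [run_null_battery()].
#' @inheritParams run_null_battery
#' @return A battery tibble with extra columns `param` and `param_value`.
#' @export
sensitivity_sweep <- function(param = c("kappa", "r_d", "r_g", "mu"), values,
                              window = plot_window(),
                              crowns = crown_uniform(2, 5),
                              net_types = c("cs", "cl", "wcl"),
                              n_sim = 199, seed = 1, d_max = 10, ...) {
  param <- match.arg(param)
  if (length(values) < 1) abort("`values` must be non-empty.")
  dplyr::bind_rows(lapply(values, function(v) {
    args <- c(setNames(list(v), param), list(...))
    models <- do.call(default_null_models, args)
    batch <- run_null_battery(
      models, window, crowns, net_types,
      n_sim = n_sim, seed = seed, d_max = d_max
    )
    batch$param <- param
    batch$param_value <- v
    batch
  }))
}
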