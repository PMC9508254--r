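small_models <- function() default_null_models()[c("csr", "thomas")]

test_that("battery shape, determinism and paired seeds", {
  b <- run_null_battery(small_models(), n_sim = 2, seed = 5, net_types = c("cs", "cl"))
  expect_equal(nrow(b), 2 * 2 * 2)
  expect_setequal(unique(b$model), c("csr", "thomas"))
  b2 <- run_null_battery(small_models(), n_sim = 2, seed = 5, net_types = c("cs", "cl"))
  expect_equal(as.data.frame(b), as.data.frame(b2))
  one <- run_null_battery(small_models()["csr"], n_sim = 2, seed = 5, net_types = "cs")
  expect_equal(nrow(one), 2)
  # replicate seeds are shared across models: the csr rows of the joint
  # battery equal a csr-only battery with the same master seed
  joint_csr <- b[b$model == "csr" & b$net_type == "cs", c("N", "E", "k")]
  expect_equal(as.data.frame(joint_csr), as.data.frame(one[, c("N", "E", "k")]))
  expect_error(run_null_battery(small_models(), n_sim = 1), "at least 2")
})

test_that("ANOVA/Tukey comparison behaves on synthetic batteries", {
  fake <- function(model, vals) {
    tibble::tibble(
      model = model, replicate = seq_along(vals), net_type = "cs", k = vals
    )
  }
  batch <- dplyr::bind_rows(
    fake("csr", c(5.0, 5.2, 5.1, 4.9)),
    fake("thomas", c(9.0, 9.4, 9.2, 9.1)),
    fake("hardcore", c(2.0, 2.2, 2.1, 1.9))
  )
  cmp <- compare_models(batch, "k", "cs")
  expect_s3_class(cmp, "crownet_comparison")
  g <- glance(cmp)
  expect_lt(g$p.value, 1e-6)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3) # all model pairs
  expect_true(all(td$p_adj >= 0 & td$p_adj <= 1))
  expect_true(all(!td$ranges_overlap))

  # identical groups: F ~ 0, Tukey p ~ 1
  same <- dplyr::bind_rows(fake("csr", c(1, 2, 3)), fake("thomas", c(1, 2, 3)))
  cmp2 <- compare_models(same, "k", "cs")
  expect_lt(glance(cmp2)$statistic, 1e-10)
  expect_gt(tidy(cmp2)$p_adj[1], 0.999)

  # zero within-group variance is flagged
  flat <- dplyr::bind_rows(fake("csr", c(1, 1, 1)), fake("thomas", c(2, 2, 2)))
  expect_warning(compare_models(flat, "k", "cs"), "Zero within-model")

  expect_error(compare_models(fake("csr", 1:3), "k", "cs"), "at least 2 models")
  expect_error(compare_models(batch, "nope", "cs"), "not a column")
})

test_that("metric verdicts require significance and disjoint ranges", {
  fake <- function(model, vals) {
    tibble::tibble(
      model = model, replicate = seq_along(vals), net_type = "cs", k = vals
    )
  }
  separated <- dplyr::bind_rows(
    fake("csr", c(5.0, 5.2, 5.1)),
    fake("matern", c(9.0, 9.3, 9.2)),
    fake("thomas", c(10.0, 10.3, 10.1)),
    fake("hardcore", c(2.0, 2.2, 2.1)),
    fake("strauss", c(3.0, 3.2, 3.1))
  )
  v <- classify_metric(separated, "k", "cs")
  expect_true(v$distinguishing)
  expect_equal(v$n_pairs, 8) # cross-group pairs among 5 models

  # overlap between csr and strauss ranges destroys the verdict
  overlapping <- dplyr::bind_rows(
    separated[separated$model != "strauss", ],
    fake("strauss", c(4.0, 5.05, 4.5))
  )
  v2 <- classify_metric(overlapping, "k", "cs")
  expect_false(v2$distinguishing)
  expect_equal(v2$n_disjoint, 7)

  expect_error(classify_metric(fake("csr", 1:3), "k", "cs"), "at least 2 models")
  both <- classify_metrics(separated, metrics = c("k"), net_type = "cs")
  expect_equal(nrow(both), 1)
})

test_that("empirical stands are located within the null distributions", {
  obs <- simulate_pattern("csr", plot_window(70, 70), seed = 31)
  obs <- assign_crown_radii(obs, crown_uniform(2, 5), seed = 32)
  res <- empirical_vs_null(obs,
    net_types = "cs", n_sim = 19, seed = 7,
    metrics = c("k", "C")
  )
  expect_setequal(unique(res$model), c("csr", "matern", "thomas", "hardcore", "strauss"))
  expect_true(all(res$percentile >= 0 & res$percentile <= 100))
  # the generating model should not reject its own data
  csr_k <- res[res$model == "csr" & res$metric == "k", ]
  expect_true(csr_k$in_range)
  # a cluster battery at matched *total* intensity sits far above CSR data
  thomas_k <- res[res$model == "thomas" & res$metric == "k", ]
  expect_lte(thomas_k$percentile, 5)
})

test_that("a single-point sensitivity sweep reduces to the plain battery", {
  swp <- sensitivity_sweep("kappa", 0.015,
    n_sim = 2, seed = 3, net_types = "cs"
  )
  base <- run_null_battery(default_null_models(kappa = 0.015),
    n_sim = 2, seed = 3, net_types = "cs"
  )
  expect_equal(swp$E, base$E)
  expect_equal(unique(swp$param), "kappa")
  expect_equal(unique(swp$param_value), 0.015)
  swp2 <- sensitivity_sweep("kappa", 0.015, n_sim = 2, seed = 3, net_types = "cs")
  expect_equal(swp$E, swp2$E) # deterministic under a fixed seed
})
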