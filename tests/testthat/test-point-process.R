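test_that("CSR counts follow the Poisson mean and respect the window", {
  counts <- vapply(
    seq_len(199),
    function(i) nrow(simulate_pattern("csr", seed = 1000 + i)),
    numeric(1)
  )
  expect_lt(abs(mean(counts) - 600), 3 * sqrt(600 / 199))
  pat <- simulate_pattern("csr", plot_window(50, 30, xmin = 10, ymin = 5), seed = 1)
  expect_true(all(pat$x >= 10 & pat$x <= 60))
  expect_true(all(pat$y >= 5 & pat$y <= 35))
})

test_that("invalid null-model parameters are rejected", {
  expect_error(null_model("csr", kappa = -1), "kappa")
  expect_error(null_model("matern", mu = 0), "mu")
  expect_error(null_model("thomas", r_d = -2), "r_d")
  expect_error(null_model("strauss", p = 1.5), "p")
  expect_error(null_model("hardcore", r_g = 0), "r_g")
})

test_that("cluster offspring stay within the dispersal range of their parent", {
  pat <- simulate_pattern("matern", seed = 7)
  par <- attr(pat, "parents")
  d <- sqrt((pat$x - par[, 1])^2 + (pat$y - par[, 2])^2)
  expect_true(all(d <= 5 + 1e-12))

  # degenerate dispersal: offspring coincide with parents
  pat0 <- simulate_pattern(null_model("matern", r_d = 1e-9), seed = 7)
  par0 <- attr(pat0, "parents")
  expect_lt(max(abs(pat0$x - par0[, 1])), 1e-8)

  pt0 <- simulate_pattern(null_model("thomas", sigma = 1e-9), seed = 7)
  part <- attr(pt0, "parents")
  expect_lt(max(abs(pt0$y - part[, 2])), 1e-7)
})

test_that("Thomas offspring displacements have the configured Gaussian scale", {
  pat <- simulate_pattern(null_model("thomas", sigma = 1.25), seed = 11)
  par <- attr(pat, "parents")
  dx <- pat$x - par[, 1]
  expect_lt(abs(sd(dx) - 1.25) / 1.25, 0.05)
})

test_that("cluster counts respect the chosen intensity convention", {
  counts <- vapply(seq_len(100), function(i) {
    nrow(simulate_pattern(null_model("matern"), seed = 2000 + i))
  }, numeric(1))
  # Var(N) ~ E[parents] * (mu + mu^2) for a Poisson cluster process
  se <- sqrt(200 * 12 / 100)
  expect_lt(abs(mean(counts) - 600), 3 * se) # total: kappa * |W|
  parents <- vapply(seq_len(60), function(i) {
    nrow(simulate_pattern(null_model("matern", kappa_is = "parents"), seed = 3000 + i))
  }, numeric(1))
  se_p <- sqrt(600 * 12 / 60)
  expect_lt(abs(mean(parents) - 1800), 3 * se_p) # parents: kappa * mu * |W|
})

test_that("hard-core patterns never contain pairs closer than r_g", {
  for (i in 1:5) {
    pat <- simulate_pattern("hardcore", seed = 40 + i)
    expect_gte(min(dist(cbind(pat$x, pat$y))), 4)
  }
  # fixed-n variant honours the hard core too
  patf <- simulate_pattern(null_model("hardcore", n_mode = "fixed"), seed = 3)
  expect_gte(min(dist(cbind(patf$x, patf$y))), 4)
  expect_equal(nrow(patf), round(0.015 * 40000))
})

test_that("Strauss interpolates between hard-core and CSR", {
  close_pairs <- function(pat, rg = 4) sum(dist(cbind(pat$x, pat$y)) < rg)
  cp <- vapply(1:5, function(i) {
    c(
      csr = close_pairs(simulate_pattern("csr", seed = 60 + i)),
      str = close_pairs(simulate_pattern("strauss", seed = 60 + i)),
      hc = close_pairs(simulate_pattern("hardcore", seed = 60 + i))
    )
  }, numeric(3))
  expect_true(all(cp["hc", ] == 0))
  expect_gt(mean(cp["str", ]), 0)
  expect_lt(mean(cp["str", ]), mean(cp["csr", ]))
  # p = 1 removes the inhibition entirely: counts revert to Poisson(kappa*|W|)
  n1 <- vapply(1:10, function(i) {
    nrow(simulate_pattern(null_model("strauss", p = 1), seed = 80 + i))
  }, numeric(1))
  expect_lt(abs(mean(n1) - 600), 3 * sqrt(600 / 10))
  # p = 0 is the hard-core process
  p0 <- simulate_pattern(null_model("strauss", p = 0), seed = 90)
  expect_gte(min(dist(cbind(p0$x, p0$y))), 4)
})

test_that("simulation is reproducible given a seed", {
  for (m in c("csr", "matern", "thomas", "hardcore", "strauss")) {
    a <- simulate_pattern(m, seed = 123)
    b <- simulate_pattern(m, seed = 123)
    expect_identical(a$x, b$x)
    expect_identical(a$y, b$y)
  }
  a <- simulate_pattern("csr", seed = 1)
  b <- simulate_pattern("csr", seed = 2)
  expect_false(identical(a$x, b$x))
})

test_that("random labelling attaches crown radii without touching positions", {
  pat <- simulate_pattern("csr", seed = 5)
  lab <- assign_crown_radii(pat, crown_uniform(2, 5), seed = 6)
  expect_identical(lab$x, pat$x)
  expect_true(all(lab$crown_radius >= 2 & lab$crown_radius <= 5))
  eps <- 1e-9
  deg <- assign_crown_radii(pat, crown_uniform(3, 3 + eps), seed = 6)
  expect_lt(max(abs(deg$crown_radius - 3)), 1e-8)
})

test_that("gamma crown fits recover known parameters", {
  set.seed(99)
  r <- rgamma(5000, shape = 4, rate = 2)
  fit <- fit_crown_gamma(r)
  expect_lt(abs(fit$shape - 4) / 4, 0.1)
  expect_lt(abs(fit$rate - 2) / 2, 0.1)

  expo <- rgamma(5000, shape = 1, rate = 0.5)
  fit2 <- fit_crown_gamma(expo)
  expect_lt(abs(fit2$shape - 1), 0.1)

  expect_error(fit_crown_gamma(rep(3, 100)), "degenerate")
  expect_error(fit_crown_gamma(c(-1, r[1:20])), "positive")
  expect_error(fit_crown_gamma(r[1:5]), "at least 10")

  # fit -> sample -> refit round trip stays near the first fit
  set.seed(100)
  refit <- fit_crown_gamma(rgamma(5000, shape = fit$shape, rate = fit$rate))
  expect_lt(abs(refit$shape - fit$shape) / fit$shape, 0.15)
})

test_that("intensity estimates are count over area", {
  pat <- as_tree_pattern(toy_trees(271, seed = 1, width = 100, height = 100),
    window = plot_window(100, 100)
  )
  expect_equal(estimate_intensity(pat), 0.0271)
  p2 <- as_tree_pattern(toy_trees(600, seed = 2, width = 200, height = 200),
    window = plot_window(200, 200)
  )
  expect_equal(estimate_intensity(p2), 0.015)
  expect_equal(estimate_intensity(p2, window = plot_window(400, 400)), 0.00375)
  expect_warning(
    z <- estimate_intensity(
      tibble::tibble(x = numeric(), y = numeric()),
      window = plot_window(10, 10)
    ),
    "Empty"
  )
  expect_equal(z, 0)
})
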