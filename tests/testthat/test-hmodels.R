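test_that("family densities are proper (integrate/sum to one)", {
  # gaussian / negative binomial via base distributions
  expect_equal(sum(exp(loglik("negbinomial_log", list(mu = 4.2, size = 2.5),
                              0:500))), 1, tolerance = 1e-6)
  # mean-precision beta
  expect_equal(integrate(function(y) dbeta_mu(y, 0.3, 7), 0, 1)$value, 1,
               tolerance = 1e-6)
  # zero-inflated beta: point mass + interior density
  zib_int <- integrate(function(y) dzibeta(y, 0.4, 5, zi = 0.25), 1e-12,
                       1 - 1e-12)$value
  expect_equal(zib_int + 0.25, 1, tolerance = 1e-6)
  # zero-one-inflated beta: two point masses + interior
  zoib_int <- integrate(function(y) dzoibeta(y, 0.6, 4, zoi = 0.3, coi = 0.7),
                        1e-12, 1 - 1e-12)$value
  expect_equal(zoib_int + 0.3 * 0.7 + 0.3 * 0.3, 1, tolerance = 1e-6)
})

test_that("inflated mixtures reduce to their limiting cases", {
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_equal(dzoibeta(grid, 0.45, 6, zoi = 0, coi = 0.5, log = TRUE),
               dbeta_mu(grid, 0.45, 6, log = TRUE), tolerance = 1e-12)
  expect_equal(dzibeta(0, 0.5, 5, zi = 0.3, log = TRUE), log(0.3))
  # negative binomial approaches Poisson as dispersion grows
  k <- 0:10
  expect_equal(loglik("negbinomial_log", list(mu = exp(1), size = 1e8), k),
               dpois(k, exp(1), log = TRUE), tolerance = 1e-6)
  expect_error(loglik("beta_logit", list(mu = 0.5, phi = 2), c(0.5, 1)),
               "support")
  expect_error(dzibeta(1, 0.5, 5, 0.2), "support")
})

test_that("design assembly derives the sampling covariates", {
  sv <- two_year_survey()
  m <- community_matrix(sv)
  tabs <- list(samples = sample_info(m), states = diversity_state(m))
  d <- assemble_design(tabs, unit = "plot")
  expect_equal(d$ln_plot_size, c(0, 0))  # 1 m2 plots
  expect_equal(d$duration, c(6, 6))
  p1 <- d[d$plot == "p1", ]
  expect_equal(p1$mean_richness, 3)      # 3 species both years
  expect_equal(p1$richness_last, 3L)

  dy <- assemble_design(tabs, unit = "plot_year")
  expect_equal(sort(unique(dy$year_c)), c(-3, 3))  # years 2000/2006 centred

  expect_error(assemble_design(tabs, unit = "plot",
                               require = "temp_change_c_yr"),
               "not derivable.*temp_change_c_yr")
})

test_that("gaussian intercept-only fit collapses onto constant data", {
  d <- data.frame(y = rep(5, 40))
  f <- fit_hmodel(hier_spec("y", "gaussian"), d, chains = 2, iter = 500,
                  warmup = 250, seed = 1)
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 5, tolerance = 1e-3)
  expect_lt(co$estimate[co$term == "sigma"], 0.01)
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(1)
  d <- data.frame(y = rpois(60, 6), x = rnorm(60))
  spec <- hier_spec("y", "negbinomial_log", fixed = "x")
  f1 <- fit_hmodel(spec, d, chains = 2, iter = 400, warmup = 200, seed = 42)
  f2 <- fit_hmodel(spec, d, chains = 2, iter = 400, warmup = 200, seed = 42)
  expect_identical(f1$coefficients, f2$coefficients)
  f3 <- fit_hmodel(spec, d, chains = 2, iter = 400, warmup = 200, seed = 43)
  expect_false(identical(f1$coefficients$estimate, f3$coefficients$estimate))
})

test_that("a single-level grouping drops the random term with a warning", {
  set.seed(2)
  d <- data.frame(y = rnorm(30), g = "only")
  expect_warning(
    f <- fit_hmodel(hier_spec("y", "gaussian", random = ranef_intercept("g")),
                    d, chains = 2, iter = 400, warmup = 200, seed = 1),
    "random term dropped")
  expect_true(f$diagnostics$dropped_random)
})

test_that("each family recovers its simulation parameters (coverage over replicates)", {
  # intercept + slope models, n = 500, 20 seeded replicates per family;
  # the nominal 95% interval should cover the true slope in >= 90%
  fams <- list(
    gaussian = function(eta) rnorm(length(eta), eta, 0.8),
    negbinomial_log = function(eta) rnbinom(length(eta), mu = exp(eta), size = 5),
    beta_logit = function(eta) {
      mu <- plogis(eta); phi <- 8
      rbeta(length(eta), mu * phi, (1 - mu) * phi)
    },
    zi_beta_logit = function(eta) {
      mu <- plogis(eta); phi <- 8
      y <- rbeta(length(eta), mu * phi, (1 - mu) * phi)
      y[runif(length(eta)) < 0.3] <- 0
      y
    },
    zoi_beta_logit = function(eta) {
      mu <- plogis(eta); phi <- 8
      y <- rbeta(length(eta), mu * phi, (1 - mu) * phi)
      b <- runif(length(eta)) < 0.25
      y[b] <- rbinom(sum(b), 1, 0.6)
      y
    })
  truth <- c(gaussian = 0.5, negbinomial_log = 0.3, beta_logit = 0.4,
             zi_beta_logit = 0.4, zoi_beta_logit = 0.4)
  intercepts <- c(gaussian = 1, negbinomial_log = 1.2, beta_logit = -0.2,
                  zi_beta_logit = -0.2, zoi_beta_logit = -0.2)
  for (fam in names(fams)) {
    covered <- 0
    for (r in 1:20) {
      set.seed(5000 + r)
      x <- rnorm(500)
      eta <- intercepts[[fam]] + truth[[fam]] * x
      d <- data.frame(y = fams[[fam]](eta), x = x)
      # interior-only support for the plain beta family
      if (fam == "beta_logit") d$y <- pmin(pmax(d$y, 1e-6), 1 - 1e-6)
      f <- fit_hmodel(hier_spec("y", fam, fixed = "x"), d, chains = 2,
                      iter = 700, warmup = 350, seed = r)
      co <- f$coefficients[f$coefficients$term == "x", ]
      covered <- covered + (co$lower <= truth[[fam]] &&
                              co$upper >= truth[[fam]])
    }
    expect_gte(covered, 18)
  }
})

test_that("zero-inflation probability is recovered", {
  set.seed(33)
  y <- rbeta(600, 0.5 * 6, 0.5 * 6)
  y[runif(600) < 0.3] <- 0
  f <- fit_hmodel(hier_spec("y", "zi_beta_logit"), data.frame(y = y),
                  chains = 2, iter = 800, warmup = 400, seed = 2)
  co <- f$coefficients
  expect_equal(co$estimate[co$term == "zi"], 0.3, tolerance = 0.05)
  expect_equal(plogis(co$estimate[co$term == "(Intercept)"]), 0.5,
               tolerance = 0.05)
})

test_that("estimates agree with an independent likelihood-based fit", {
  skip_if_not_installed("glmmTMB")
  set.seed(9)
  J <- 20
  d <- data.frame(g = rep(sprintf("g%02d", 1:J), each = 15),
                  x = rnorm(J * 15))
  u <- rnorm(J, 0, 0.4)
  d$y <- rnbinom(nrow(d), mu = exp(1 + 0.4 * d$x + u[as.integer(factor(d$g))]),
                 size = 4)
  f <- fit_hmodel(hier_spec("y", "negbinomial_log", fixed = "x",
                            random = ranef_intercept("g")),
                  d, chains = 2, iter = 1500, warmup = 750, seed = 4)
  g <- glmmTMB::glmmTMB(y ~ x + (1 | g), family = glmmTMB::nbinom2, data = d)
  co <- f$coefficients
  fe <- glmmTMB::fixef(g)$cond
  expect_equal(co$estimate[co$term == "x"], unname(fe["x"]), tolerance = 0.05)
  expect_equal(co$estimate[co$term == "(Intercept)"],
               unname(fe["(Intercept)"]), tolerance = 0.1)
})

test_that("the model suite runs its battery and records failures without stopping", {
  sim <- small_sim(seed = 13)
  tb <- pipeline_tables(sim$survey, sim$climate)
  out <- run_model_suite(tb, models = c("spatial_richness_geo", "nonsense"),
                         chains = 2, iter = 400, warmup = 200, seed = 1)
  expect_named(out$fits, "spatial_richness_geo")
  expect_match(out$errors[["nonsense"]], "unknown model")
  expect_true(all(c("model", "term", "estimate", "lower", "upper") %in%
                    names(out$coefficients)))
})

test_that("the suite recovers an injected shrub-loss effect", {
  sim <- generate_synthetic(scenario("shrubification", seed = 21))
  tb <- pipeline_tables(sim$survey, sim$climate)
  out <- run_model_suite(tb, models = "richness_change_fg_shrub",
                         chains = 2, iter = 800, warmup = 400, seed = 3)
  co <- out$fits$richness_change_fg_shrub$coefficients
  expect_lt(co$estimate[co$term == "shrub_change"], 0)
})
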