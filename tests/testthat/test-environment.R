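gv_table <- function(g, trait_id = 0L) {
  tibble::tibble(individual_id = seq_along(g) - 1L, trait_id = trait_id,
                 genetic_value = g)
}

test_that("genetic variance is the population (denominator-n) variance", {
  expect_equal(genetic_variance(gv_table(c(0, 0.05, 0.1))),
               0.05^2 * (2 / 3))
  expect_equal(genetic_variance(gv_table(rep(0.3, 5))), 0)
  expect_equal(genetic_variance(gv_table(1.7)), 0) # single individual
  expect_error(genetic_variance(gv_table(numeric(0))), "No individuals")
})

test_that("h2 = 1 gives exactly zero noise and phenotype = G", {
  g <- c(0, 0.05, 0.1, 0.2)
  ph <- sim_env(gv_table(g), h2 = 1, seed = 1)
  expect_identical(ph$environmental_noise, rep(0, 4))
  expect_identical(ph$phenotype, g)
})

test_that("zero genetic variance yields zero noise even below h2 = 1", {
  ph <- sim_env(gv_table(rep(0.5, 10)), h2 = 0.4, seed = 2)
  expect_identical(ph$environmental_noise, rep(0, 10))
})

test_that("invalid heritability is rejected", {
  tab <- gv_table(c(0, 1))
  expect_error(sim_env(tab, h2 = 0), "h2")
  expect_error(sim_env(tab, h2 = -0.1), "h2")
  expect_error(sim_env(tab, h2 = 1.2), "h2")
  expect_error(sim_env(tab, h2 = c(0.5, 0.6)), "h2") # one trait, two values
})

test_that("noise variance is calibrated to V_G (1 - h2) / h2", {
  n <- 1e5
  g <- withr::with_seed(3, stats::rnorm(n, sd = 2))
  vg <- mean((g - mean(g))^2)
  ph <- sim_env(gv_table(g), h2 = 0.5, seed = 4)
  # at h2 = 0.5 the noise variance equals V_G
  ratio <- var(ph$environmental_noise) / vg
  se <- sqrt(2 / (n - 1)) # sampling SE of a variance ratio
  expect_lt(abs(ratio - 1), 4 * se)
  # and the noise mean is zero within 4 SE
  expect_lt(abs(mean(ph$environmental_noise)),
            4 * sqrt(vg) / sqrt(n))
  expect_identical(ph$phenotype, ph$genetic_value + ph$environmental_noise)
})

test_that("lowering h2 strictly inflates the noise scale for the same seed", {
  g <- withr::with_seed(5, stats::rnorm(500))
  vars <- vapply(c(0.9, 0.6, 0.3, 0.1), function(h2) {
    var(sim_env(gv_table(g), h2 = h2, seed = 6)$environmental_noise)
  }, 0)
  expect_true(all(diff(vars) > 0))
  # same seed: noise vectors are perfectly correlated scalings
  e1 <- sim_env(gv_table(g), h2 = 0.9, seed = 6)$environmental_noise
  e2 <- sim_env(gv_table(g), h2 = 0.3, seed = 6)$environmental_noise
  expect_equal(cor(e1, e2), 1)
  expect_true(all(abs(e2) >= abs(e1)))
})

test_that("per-trait heritabilities are applied trait by trait", {
  g <- withr::with_seed(7, stats::rnorm(2000))
  tab <- dplyr::bind_rows(gv_table(g, 0L), gv_table(g, 1L))
  ph <- sim_env(tab, h2 = c(1, 0.5), seed = 8)
  expect_identical(ph$environmental_noise[ph$trait_id == 0], rep(0, 2000))
  expect_gt(var(ph$environmental_noise[ph$trait_id == 1]), 0)
})

test_that("realised heritability recovers the request as n grows", {
  for (n in c(1e3, 1e4)) {
    g <- withr::with_seed(9, stats::rnorm(n))
    realised <- vapply(1:8, function(s) {
      ph <- sim_env(gv_table(g), h2 = 0.3, seed = s)
      var(ph$genetic_value) / var(ph$phenotype)
    }, 0)
    tol <- if (n == 1e3) 0.1 else 0.03
    expect_lt(abs(mean(realised) - 0.3), tol)
  }
})

test_that("the one-shot pipeline equals its three stages run with the sub-seeds", {
  arg <- make_random_arg(30, 10, n_trees = 2, stacked_mutation_rate = 0.3,
                         seed = 11)
  model <- trait_model("normal", mean = 0, var = 1)
  sim <- sim_phenotype(arg, model, h2 = 0.6, num_causal = 4, alpha = -0.2,
                       seed = 123)
  seeds <- argtrait:::derive_seeds(123, 2)
  tt <- sim_trait(arg, model, num_causal = 4, alpha = -0.2, seed = seeds[[1]])
  ph <- sim_env(genetic_values(arg, tt), h2 = 0.6, seed = seeds[[2]])
  expect_identical(sim$trait, tt)
  expect_identical(sim$phenotype, ph)
  # and the whole object reproduces under the same master seed
  again <- sim_phenotype(arg, model, h2 = 0.6, num_causal = 4, alpha = -0.2,
                         seed = 123)
  expect_identical(sim$trait, again$trait)
  expect_identical(sim$phenotype, again$phenotype)
})

test_that("with a fixed effect and h2 = 1 phenotypes equal the dosage oracle", {
  arg <- make_example_arg()
  sim <- sim_phenotype(arg, trait_model("fixed", value = 0.05), h2 = 1,
                       seed = 5)
  expect_identical(sim$phenotype$phenotype,
                   oracle_genetic_values(arg, sim$trait)$genetic_value)
})

test_that("tidy, glance and autoplot expose the simulation result", {
  arg <- make_random_arg(40, 8, seed = 13)
  sim <- sim_phenotype(arg, trait_model("normal", mean = 0, var = 1),
                       h2 = 0.8, num_causal = 3, seed = 14)
  expect_identical(generics::tidy(sim), sim$phenotype)
  expect_identical(generics::tidy(sim, "trait"), sim$trait)
  gl <- generics::glance(sim)
  expect_equal(gl$n_individuals, 20)
  expect_equal(gl$n_causal_sites, 3)
  expect_gt(gl$v_g, 0)
  p <- ggplot2::autoplot(sim)
  expect_s3_class(p, "ggplot")
})
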