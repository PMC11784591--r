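test_that("frequency scaling matches its closed form on a grid", {
  # alpha = 0 is the identity for every p
  for (p in seq(0.05, 0.95, by = 0.1)) {
    expect_identical(frequency_scale(0.05, p, 0), 0.05)
  }
  expect_equal(frequency_scale(1, 0.5, 2), 0.5)
  expect_equal(frequency_scale(1, 0.5, -1), sqrt(2))
  expect_equal(frequency_scale(0.05, 0.3, 0), 0.05)
  expect_equal(frequency_scale(2, 0.25, 2), 2 * 2 * 0.25 * 0.75)
  expect_error(frequency_scale(1, 0, 1), "strictly inside")
  expect_error(frequency_scale(1, 1, -1), "strictly inside")

  # monotone in p(1-p): decreasing for alpha < 0, increasing for alpha > 0
  p <- seq(0.05, 0.5, by = 0.05) # p(1-p) increasing on this range
  for (alpha in c(-2, -0.5, 0.5, 2)) {
    r <- frequency_scale(1, p, alpha)
    if (alpha < 0) expect_true(all(diff(r) < 0)) else
      expect_true(all(diff(r) > 0))
  }
})

test_that("causal-site selection is uniform over eligible sites", {
  arg <- make_random_arg(10, 5, seed = 3)
  elig <- argtrait:::.eligible_sites(arg)
  expect_equal(length(elig), 5)
  # exhaustive request returns every site, position-sorted
  expect_equal(select_causal_sites(arg, 5, seed = 1), sort(elig))
  expect_error(select_causal_sites(arg, 6), "5 site")

  reps <- 1e4
  hits <- withr::with_seed(99, {
    tabulate(replicate(reps, select_causal_sites(arg, 1)) + 1L, 5)
  })
  se <- sqrt(0.2 * 0.8 / reps)
  expect_true(all(abs(hits / reps - 0.2) < 4 * se))
})

test_that("monomorphic sites are ineligible and reported as errors", {
  # mutation above the root's children covering all samples -> p = 1
  arg <- make_example_arg()
  arg$mutations <- tibble::tibble(
    id = 0:1, site = 0L, node = c(6L, 9L), derived_state = "T",
    parent = NA_integer_, time = c(1.5, 2.5)
  )
  expect_equal(allele_frequency(arg, 0, "T"), 1)
  expect_error(select_causal_sites(arg, 1), "0 site")
  expect_error(choose_causal_allele(arg, 0), "no eligible causal allele")
})

test_that("causal-allele choice is uniform among segregating derived alleles", {
  arg <- triallelic_arg()
  # T on node 4 covers samples {0,1}; G on node 2 covers {2}: both segregate
  reps <- 1e4
  picks <- withr::with_seed(5, {
    replicate(reps, choose_causal_allele(arg, 0))
  })
  pr <- mean(picks == "T")
  se <- sqrt(0.25 / reps)
  expect_lt(abs(pr - 0.5), 4 * se)
  # frequency weighting shifts the choice towards the common allele
  pw <- withr::with_seed(6, {
    mean(replicate(2000, choose_causal_allele(arg, 0,
                                              weight_by_frequency = TRUE)) == "T")
  })
  expect_gt(pw, 0.58)
  # single eligible allele is returned outright
  expect_equal(choose_causal_allele(make_example_arg(), 0), "T")
})

test_that("sim_trait on the worked example returns the single causal row", {
  arg <- make_example_arg()
  tt <- sim_trait(arg, trait_model("fixed", value = 0.05), seed = 1)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$site_id, 0L)
  expect_equal(tt$causal_allele, "T")
  expect_equal(tt$raw_beta, 0.05)
  expect_equal(tt$scaled_beta, 0.05) # alpha = 0 identity
  expect_equal(tt$allele_freq, 0.5)
  expect_equal(tt$trait_id, 0L)
})

test_that("explicit causal sites pass through, as ids or position tables", {
  arg <- make_random_arg(16, 8, stacked_mutation_rate = 0.2, seed = 21)
  ids <- select_causal_sites(arg, 3, seed = 2)
  tt <- sim_trait(arg, trait_model("normal", mean = 0, var = 1),
                  causal_sites = ids, seed = 4)
  expect_equal(tt$site_id, ids)
  expect_equal(tt$position, arg$sites$position[ids + 1L])

  # as a data frame of positions with fixed effects
  df <- tibble::tibble(position = arg$sites$position[ids + 1L],
                       causal_allele = tt$causal_allele,
                       raw_beta = c(0.1, -0.2, 0.3))
  tt2 <- sim_trait(arg, trait_model("normal", mean = 0, var = 1),
                   causal_sites = df, alpha = -1, seed = 4)
  expect_equal(tt2$raw_beta, c(0.1, -0.2, 0.3))
  expect_equal(tt2$scaled_beta,
               frequency_scale(c(0.1, -0.2, 0.3), tt2$allele_freq, -1))

  expect_error(sim_trait(arg, trait_model("fixed", value = 1),
                         causal_sites = tibble::tibble(position = 12345)),
               "No site at position")
  expect_error(sim_trait(arg, trait_model("fixed", value = 1),
                         causal_sites = c(0L, 999L)), "Unknown causal site")
})

test_that("explicit and random site paths agree under the same master seed", {
  arg <- make_random_arg(16, 8, stacked_mutation_rate = 0.2, seed = 21)
  model <- trait_model("normal", mean = 0, var = 1)
  random_path <- sim_trait(arg, model, num_causal = 4, alpha = -0.5, seed = 77)
  explicit_path <- sim_trait(arg, model,
                             causal_sites = unique(random_path$site_id),
                             alpha = -0.5, seed = 77)
  expect_identical(random_path, explicit_path)
})

test_that("a pleiotropic model shares sites and draws across traits", {
  arg <- make_random_arg(16, 8, stacked_mutation_rate = 0.2, seed = 21)
  m <- trait_model("mvn", mean = c(0, 0),
                   cov = matrix(c(1, 0.9, 0.9, 1), 2))
  tt <- sim_trait(arg, m, num_causal = 4, seed = 5)
  expect_equal(nrow(tt), 8)
  expect_equal(unname(table(tt$trait_id)), c(4L, 4L), ignore_attr = TRUE)
  expect_identical(tt$site_id[tt$trait_id == 0], tt$site_id[tt$trait_id == 1])
  expect_identical(tt$causal_allele[tt$trait_id == 0],
                   tt$causal_allele[tt$trait_id == 1])
  # same-site frequencies identical across traits; scaling per site
  expect_identical(tt$allele_freq[tt$trait_id == 0],
                   tt$allele_freq[tt$trait_id == 1])
})

test_that("trait tables have one row per site-trait pair with alpha-0 identity", {
  arg <- make_random_arg(20, 10, stacked_mutation_rate = 0.4, seed = 31)
  tt <- sim_trait(arg, trait_model("normal", mean = 0, var = 1),
                  num_causal = 6, alpha = 0, seed = 8)
  expect_equal(nrow(tt), 6)
  expect_false(any(duplicated(tt[c("site_id", "trait_id")])))
  expect_identical(tt$scaled_beta, tt$raw_beta)
  expect_true(all(tt$allele_freq > 0 & tt$allele_freq < 1))
  # frequencies agree with the brute-force oracle
  for (i in seq_len(nrow(tt))) {
    expect_equal(tt$allele_freq[i],
                 oracle_freq(arg, tt$site_id[i], tt$causal_allele[i]))
  }
})
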