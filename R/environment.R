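#' Genetic variance of a trait
#'
#' The population variance (denominator n) of individual genetic values
#' G for one trait — the `V_G` entering the environmental-noise variance
#' `V_G (1 - h2) / h2`.
#'
#' @param values An individual value table as returned by
#'   [genetic_values()].
#' @param trait_id Trait id (default 0).
#' @return Non-negative variance; 0 when all G are equal (including the
#'   single-individual case).
#' @export
genetic_variance <- function(values, trait_id = 0L) {
  g <- values$genetic_value[values$trait_id == trait_id]
  if (length(g) == 0) {
    abort(sprintf("No individuals found for trait %s.", format(trait_id)))
  }
  mean((g - mean(g))^2)
}

#' Simulate environmental noise and phenotypes
#'
#' The final stage of the simulator: for each trait, environmental noise
#' is drawn i.i.d. per individual from a normal distribution with mean 0
#' and variance `V_G (1 - h2) / h2`, where `V_G` is the population
#' variance of the genetic values and `h2` the requested narrow-sense
#' heritability; the phenotype is `G + E`. At `h2 = 1` (and whenever
#' `V_G = 0`) the noise is exactly zero. Noise is drawn independently
#' per trait: pleiotropy is modelled through effect sizes only, not
#' through environmental correlation.
#'
#' @param values An individual value table as returned by
#'   [genetic_values()].
#' @param h2 Narrow-sense heritability, in `(0, 1]`: a scalar applied to
#'   every trait, or one value per trait (in ascending `trait_id`
#'   order). `h2 = 0` is rejected — the noise variance formula divides
#'   by `h2`.
#' @param seed Optional integer seed.
#' @return A phenotype table: tibble with columns `individual_id`,
#'   `trait_id`, `genetic_value`, `environmental_noise`, `phenotype`
#'   (`= genetic_value + environmental_noise` exactly).
#' @export
sim_env <- function(values, h2, seed = NULL) {
  need <- c("individual_id", "trait_id", "genetic_value")
  missing <- setdiff(need, names(values))
  if (length(missing) > 0) {
    abort(sprintf("`values` is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(values) == 0) {
    abort("`values` has no individuals: cannot simulate noise on an empty table.")
  }
  trait_ids <- sort(unique(values$trait_id))
  if (!is.numeric(h2) || !length(h2) %in% c(1L, length(trait_ids)) ||
      any(!is.finite(h2)) || any(h2 <= 0) || any(h2 > 1)) {
    abort("`h2` must be in (0, 1], one value overall or one per trait.")
  }
  h2 <- rep_len(h2, length(trait_ids))

  .with_seed(seed, {
    res <- lapply(seq_along(trait_ids), function(k) {
      tid <- trait_ids[k]
      block <- values[values$trait_id == tid, , drop = FALSE]
      block <- block[order(block$individual_id), , drop = FALSE]
      vg <- genetic_variance(block, tid)
      env_sd <- sqrt(vg * (1 - h2[k]) / h2[k])
      e <- stats::rnorm(nrow(block), mean = 0, sd = env_sd)
      tibble(
        individual_id = block$individual_id,
        trait_id = tid,
        genetic_value = block$genetic_value,
        environmental_noise = e,
        phenotype = block$genetic_value + e
      )
    })
    dplyr::bind_rows(res)
  })
}

#' One-shot phenotype simulation
#'
#' Runs the full pipeline — [sim_trait()] then [genetic_values()] then
#' [sim_env()] — on an ARG. The master `seed` spawns one sub-stream per
#' stochastic stage in a fixed order (trait simulation, then noise), so
#' the one-shot call is exactly the composition of the three stages run
#' manually with those sub-seeds.
#'
#' @inheritParams sim_trait
#' @param h2 Narrow-sense heritability in `(0, 1]` (scalar or per
#'   trait); see [sim_env()].
#' @return A `phenotype_sim` object: list with `trait` (the
#'   [sim_trait()] table) and `phenotype` (the [sim_env()] table), plus
#'   the call parameters. Supports [print()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' arg <- make_example_arg()
#' sim <- sim_phenotype(arg, trait_model("fixed", value = 0.05), h2 = 1,
#'                      seed = 1)
#' sim$phenotype
#' @export
sim_phenotype <- function(arg, model, h2, num_causal = 1,
                          causal_sites = NULL, alpha = 0,
                          weight_by_frequency = FALSE, seed = NULL) {
  validate_arg(arg)
  model <- validate_model(model)
  seeds <- derive_seeds(seed, 2)
  trait <- sim_trait(arg, model, num_causal = num_causal,
                     causal_sites = causal_sites, alpha = alpha,
                     weight_by_frequency = weight_by_frequency,
                     seed = seeds[[1]])
  gv <- genetic_values(arg, trait)
  phen <- sim_env(gv, h2, seed = seeds[[2]])
  structure(
    list(trait = trait, phenotype = phen, model = model, alpha = alpha,
         h2 = h2, seed = seed),
    class = "phenotype_sim"
  )
}

#' @export
print.phenotype_sim <- function(x, ...) {
  cat(sprintf(
    "<phenotype_sim> %d causal site(s), %d trait(s), %d individual(s), h2 = %s\n",
    length(unique(x$trait$site_id)), length(unique(x$trait$trait_id)),
    length(unique(x$phenotype$individual_id)),
    paste(format(x$h2), collapse = ", ")))
  cat("$trait\n"); print(x$trait)
  cat("$phenotype\n"); print(x$phenotype)
  invisible(x)
}

#' Tidy a phenotype simulation
#'
#' @param x A `phenotype_sim` object.
#' @param table Which table to return: `"phenotype"` (default) or
#'   `"trait"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy phenotype_sim
#' @export
tidy.phenotype_sim <- function(x, table = c("phenotype", "trait"), ...) {
  switch(match.arg(table), phenotype = x$phenotype, trait = x$trait)
}

#' One-row summary of a phenotype simulation
#'
#' @param x A `phenotype_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: individual/trait/causal-site counts, the
#'   mean (across traits) genetic variance `v_g`, and the mean realised
#'   heritability `Var(G)/Var(P)` (`NA` when phenotypic variance is 0).
#' @method glance phenotype_sim
#' @export
glance.phenotype_sim <- function(x, ...) {
  per_trait <- x$phenotype |>
    dplyr::group_by(.data$trait_id) |>
    dplyr::summarise(
      v_g = mean((.data$genetic_value - mean(.data$genetic_value))^2),
      v_p = mean((.data$phenotype - mean(.data$phenotype))^2),
      .groups = "drop"
    )
  tibble(
    n_individuals = length(unique(x$phenotype$individual_id)),
    n_traits = nrow(per_trait),
    n_causal_sites = length(unique(x$trait$site_id)),
    v_g = mean(per_trait$v_g),
    realized_h2 = mean(ifelse(per_trait$v_p > 0,
                              per_trait$v_g / per_trait$v_p, NA_real_))
  )
}

#' Plot a phenotype simulation
#'
#' Histograms of the simulated phenotype per trait, with the genetic
#' values overlaid, giving a quick visual check of how much phenotypic
#' spread the environmental noise adds at the requested heritability.
#'
#' @param object A `phenotype_sim` object.
#' @param bins Number of histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phenotype_sim
#' @export
autoplot.phenotype_sim <- function(object, bins = 30, ...) {
  df <- object$phenotype |>
    tidyr::pivot_longer(c("genetic_value", "phenotype"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$component)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait_id),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "value", y = "individuals",
                  title = sprintf("Simulated phenotypes (h2 = %s)",
                                  paste(format(object$h2), collapse = ", ")))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
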