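#' Frequency-dependent effect-size scaling
#'
#' Scales a raw effect size by `(2 p (1 - p))^(alpha / 2)`, where `p` is
#' the causal-allele frequency and `alpha` controls the strength of
#' frequency dependence: `alpha = 0` leaves `beta` unchanged, negative
#' `alpha` up-weights rare variants, positive `alpha` up-weights common
#' ones. Vectorised over its arguments.
#'
#' @param raw_beta Raw effect size(s).
#' @param p Causal-allele frequency, strictly inside `(0, 1)`.
#' @param alpha Frequency-dependence exponent (finite real, default 0).
#' @return `raw_beta * (2 * p * (1 - p))^(alpha / 2)`.
#' @examples
#' frequency_scale(1, p = 0.5, alpha = 2)   # 0.5
#' frequency_scale(1, p = 0.5, alpha = -1)  # sqrt(2)
#' @export
frequency_scale <- function(raw_beta, p, alpha = 0) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1): the frequency scaling is degenerate at p = 0 or 1.")
  }
  if (!is.numeric(alpha) || any(!is.finite(alpha))) {
    abort("`alpha` must be finite.")
  }
  raw_beta * (2 * p * (1 - p))^(alpha / 2)
}

# Derived alleles segregating among the samples at one site, i.e. the
# alleles eligible to be causal: observed among sample nodes, distinct
# from the ancestral state, frequency strictly in (0, 1).
.eligible_alleles <- function(arg, site, tree = NULL, children = NULL) {
  srow <- .site_row(arg, site)
  fr <- .sample_state_freqs(arg, site, tree, children)
  fr <- fr[fr$allele != srow$ancestral_state & fr$p > 0 & fr$p < 1, ,
           drop = FALSE]
  fr
}

# Site ids with at least one eligible derived allele.
.eligible_sites <- function(arg, ctx = NULL) {
  if (nrow(arg$sites) == 0) return(integer())
  ctx <- ctx %||% .tree_ctx(arg)
  keep <- vapply(seq_len(nrow(arg$sites)), function(i) {
    tc <- ctx(arg$sites$position[i])
    nrow(.eligible_alleles(arg, arg$sites$id[i], tc$tree, tc$children)) > 0
  }, logical(1))
  arg$sites$id[keep]
}

#' Select causal sites at random
#'
#' Draws `num_causal` causal sites uniformly without replacement from the
#' eligible sites of the ARG (those with at least one derived allele
#' segregating among the samples, i.e. frequency strictly in `(0, 1)`).
#' Monomorphic-in-sample sites carry no association signal and the
#' frequency scaling is degenerate there, so they are never eligible.
#'
#' @param arg An [arg_tables()] object.
#' @param num_causal Number of causal sites (positive integer).
#' @param seed Optional integer seed.
#' @return Integer vector of site ids, sorted by genome position.
#' @export
select_causal_sites <- function(arg, num_causal = 1, seed = NULL) {
  validate_arg(arg)
  num_causal <- .check_count(num_causal, "num_causal")
  elig <- .eligible_sites(arg)
  if (num_causal > length(elig)) {
    abort(sprintf(
      "Requested %d causal sites but only %d site(s) are eligible (derived allele segregating among samples).",
      num_causal, length(elig)))
  }
  chosen <- .with_seed(seed, .sample_vec(elig, num_causal))
  # Site ids are position-ordered by construction, so sorting ids sorts
  # by position.
  sort(chosen)
}

#' Choose the causal allele at a site
#'
#' Uniform choice among the distinct derived alleles segregating among
#' the samples at the site. With `weight_by_frequency = TRUE` the choice
#' is instead proportional to each allele's sample frequency.
#'
#' @param arg An [arg_tables()] object.
#' @param site Site id.
#' @param weight_by_frequency Weight the choice by allele frequency
#'   (default `FALSE`: uniform).
#' @param seed Optional integer seed.
#' @return The causal allele string.
#' @export
choose_causal_allele <- function(arg, site, weight_by_frequency = FALSE,
                                 seed = NULL) {
  validate_arg(arg)
  el <- .eligible_alleles(arg, site)
  if (nrow(el) == 0) {
    abort(sprintf(
      "Site %d has no eligible causal allele: no derived allele segregates among the samples.",
      site))
  }
  .with_seed(seed, {
    if (nrow(el) == 1L) el$allele else if (weight_by_frequency) {
      sample(el$allele, 1, prob = el$p)
    } else {
      sample(el$allele, 1)
    }
  })
}

#' Simulate causal sites and effect sizes
#'
#' The first stage of the simulator: pick causal sites (randomly, or as
#' supplied), choose a causal allele per site, draw one effect-size
#' vector per site from the trait model (shared across the k traits of a
#' multivariate model), and apply the frequency-dependent scaling
#' `(2p(1-p))^(alpha/2)` with each site's own causal-allele frequency.
#'
#' A master `seed` spawns three fixed-order sub-streams (site selection,
#' allele choice, effect sizes), so supplying the sites explicitly does
#' not perturb the allele or effect-size draws: the explicit-site path
#' reproduces the random path exactly when given the sites the random
#' path would have selected under the same master seed.
#'
#' @param arg An [arg_tables()] object.
#' @param model A [trait_model()].
#' @param num_causal Number of causal sites to pick at random (default
#'   1). Ignored when `causal_sites` is supplied.
#' @param causal_sites Optional explicit causal sites: either an integer
#'   vector of site ids, or a data frame with column `position` and
#'   optional columns `causal_allele` and `raw_beta` (matching the CSV
#'   accepted by the command-line interface). When `raw_beta` is present
#'   it must be complete and the model must be univariate.
#' @param alpha Frequency-dependence exponent (default 0, no scaling).
#' @param weight_by_frequency Passed to [choose_causal_allele()].
#' @param seed Optional integer master seed.
#' @return A trait table: tibble with columns `site_id`, `position`,
#'   `causal_allele`, `raw_beta`, `scaled_beta`, `allele_freq`,
#'   `trait_id` (0-based), one row per causal site and trait, ordered by
#'   trait then position.
#' @export
sim_trait <- function(arg, model, num_causal = 1, causal_sites = NULL,
                      alpha = 0, weight_by_frequency = FALSE, seed = NULL) {
  validate_arg(arg)
  model <- validate_model(model)
  alpha <- .check_scalar_num(alpha, "alpha")
  seeds <- derive_seeds(seed, 3)
  ctx <- .tree_ctx(arg)

  given_allele <- NULL
  given_beta <- NULL
  if (is.null(causal_sites)) {
    num_causal <- .check_count(num_causal, "num_causal")
    elig_sites <- .eligible_sites(arg, ctx)
    if (num_causal > length(elig_sites)) {
      abort(sprintf(
        "Requested %d causal sites but only %d site(s) are eligible (derived allele segregating among samples).",
        num_causal, length(elig_sites)))
    }
    sites <- sort(.with_seed(seeds[[1]], .sample_vec(elig_sites, num_causal)))
  } else if (is.data.frame(causal_sites)) {
    if (!"position" %in% names(causal_sites)) {
      abort("Explicit `causal_sites` data frame needs a `position` column.")
    }
    idx <- match(causal_sites$position, arg$sites$position)
    if (anyNA(idx)) {
      abort(sprintf("No site at position(s): %s.",
                    paste(causal_sites$position[is.na(idx)], collapse = ", ")))
    }
    ord <- order(idx)
    sites <- arg$sites$id[idx][ord]
    if ("causal_allele" %in% names(causal_sites)) {
      given_allele <- as.character(causal_sites$causal_allele)[ord]
    }
    if ("raw_beta" %in% names(causal_sites)) {
      given_beta <- as.numeric(causal_sites$raw_beta)[ord]
      if (anyNA(given_beta)) {
        abort("`raw_beta` in explicit `causal_sites` must be complete when supplied.")
      }
      if (model$num_traits > 1L) {
        abort("Supplied `raw_beta` requires a univariate trait model.")
      }
    }
  } else {
    sites <- sort(as.integer(causal_sites))
    if (any(!sites %in% arg$sites$id)) {
      abort(sprintf("Unknown causal site id(s): %s.",
                    paste(setdiff(sites, arg$sites$id), collapse = ", ")))
    }
    if (anyDuplicated(sites)) {
      abort("Explicit causal site ids must be distinct.")
    }
  }
  m <- length(sites)

  # Per-site eligible alleles (and their frequencies), computed once.
  elig <- lapply(sites, function(s) {
    tc <- ctx(arg$sites$position[match(s, arg$sites$id)])
    .eligible_alleles(arg, s, tc$tree, tc$children)
  })

  alleles <- .with_seed(seeds[[2]], {
    vapply(seq_len(m), function(i) {
      el <- elig[[i]]
      if (!is.null(given_allele)) {
        a <- given_allele[i]
        if (!a %in% el$allele) {
          abort(sprintf(
            "Allele '%s' is not an eligible causal allele at site %d (needs a derived allele with frequency in (0,1)).",
            a, sites[i]))
        }
        return(a)
      }
      if (nrow(el) == 0) {
        abort(sprintf(
          "Site %d has no eligible causal allele: no derived allele segregates among the samples.",
          sites[i]))
      }
      if (nrow(el) == 1L) el$allele
      else if (weight_by_frequency) sample(el$allele, 1, prob = el$p)
      else sample(el$allele, 1)
    }, "")
  })
  p <- vapply(seq_len(m), function(i) {
    elig[[i]]$p[match(alleles[i], elig[[i]]$allele)]
  }, 0)

  betas <- if (is.null(given_beta)) {
    .with_seed(seeds[[3]], .draw_effect_matrix(model, m))
  } else {
    matrix(given_beta, ncol = 1L)
  }

  k <- model$num_traits
  out <- tidyr::expand_grid(trait_id = seq_len(k) - 1L, row = seq_len(m))
  tibble(
    site_id = sites[out$row],
    position = arg$sites$position[match(sites[out$row], arg$sites$id)],
    causal_allele = alleles[out$row],
    raw_beta = betas[cbind(out$row, out$trait_id + 1L)],
    scaled_beta = frequency_scale(betas[cbind(out$row, out$trait_id + 1L)],
                                  p[out$row], alpha),
    allele_freq = p[out$row],
    trait_id = out$trait_id
  )
}
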