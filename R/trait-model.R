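#' Effect-size distribution models
#'
#' Constructs the distribution from which per-site effect sizes `beta`
#' are drawn. Five univariate families are supported plus a multivariate
#' normal for pleiotropic traits (one joint draw per causal site shared
#' across traits):
#'
#' * `"normal"`: `mean`, `var` (variance, > 0).
#' * `"fixed"`: `value` — deterministic, every draw equals `value`.
#' * `"exponential"`: `scale` (> 0), `random_sign` (default `TRUE`;
#'   multiplies each draw by an equiprobable +/- 1 so effect sizes admit
#'   negative values).
#' * `"gamma"`: `shape`, `scale` (> 0), `random_sign` (default `TRUE`).
#' * `"t"` (alias `"student-t"`): `mean`, `var`, `df` — a standard t
#'   scaled to the requested variance then shifted; `df <= 2` (infinite
#'   variance) is rejected.
#' * `"mvn"` (alias `"multivariate-normal"`): `mean` vector of length k,
#'   `cov` k x k symmetric positive semi-definite matrix; `num_traits`
#'   equals k.
#'
#' @param name Distribution name (see above).
#' @param ... Named distribution parameters.
#' @return A validated `trait_model` object with fields `name`, `params`
#'   and `num_traits`.
#' @examples
#' trait_model("normal", mean = 0, var = 1)
#' trait_model("fixed", value = 0.05)
#' trait_model("mvn", mean = c(0, 0), cov = diag(2))
#' @export
trait_model <- function(name, ...) {
  aliases <- c("student-t" = "t", "multivariate-normal" = "mvn",
               "multivariate_normal" = "mvn")
  if (name %in% names(aliases)) name <- unname(aliases[name])
  params <- list(...)
  num_traits <- if (identical(name, "mvn")) length(params$mean) else 1L
  validate_model(structure(
    list(name = name, params = params, num_traits = as.integer(num_traits)),
    class = "trait_model"
  ))
}

#' Validate a trait model
#'
#' @param spec A `trait_model` object (see [trait_model()]).
#' @return `spec`, or an error naming the offending parameter.
#' @export
validate_model <- function(spec) {
  if (!inherits(spec, "trait_model")) {
    abort("`spec` must be a `trait_model` object (see `trait_model()`).")
  }
  p <- spec$params
  bad <- function(field, msg) {
    abort(sprintf("Invalid trait model parameter `%s`: %s", field, msg))
  }
  need_pos <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0) {
      bad(field, "must be a single strictly positive number.")
    }
  }
  need_num <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(field, "must be a single finite number.")
    }
  }
  switch(spec$name,
    normal = { need_num("mean"); need_pos("var") },
    fixed = need_num("value"),
    exponential = need_pos("scale"),
    gamma = { need_pos("shape"); need_pos("scale") },
    t = {
      need_num("mean"); need_pos("var")
      need_pos("df")
      if (p$df <= 2) bad("df", "must exceed 2 for the variance to be finite.")
    },
    mvn = {
      if (is.null(p$mean) || !is.numeric(p$mean) || length(p$mean) < 1 ||
          any(!is.finite(p$mean))) {
        bad("mean", "must be a finite numeric vector.")
      }
      k <- length(p$mean)
      if (k != spec$num_traits) {
        bad("mean", "length must equal num_traits.")
      }
      cv <- p$cov
      if (is.null(cv) || !is.matrix(cv) || !all(dim(cv) == k) ||
          any(!is.finite(cv))) {
        bad("cov", sprintf("must be a finite %d x %d matrix.", k, k))
      }
      if (!isSymmetric(unname(cv), tol = 1e-8)) {
        bad("cov", "must be symmetric.")
      }
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1)) {
        bad("cov", "must be positive semi-definite.")
      }
    },
    abort(sprintf(
      "Unknown trait model '%s'; supported: normal, fixed, exponential, gamma, t (student-t), mvn (multivariate-normal).",
      spec$name))
  )
  if (!is.null(p$random_sign) &&
      (!is.logical(p$random_sign) || length(p$random_sign) != 1L ||
       is.na(p$random_sign))) {
    bad("random_sign", "must be TRUE or FALSE.")
  }
  spec
}

#' Draw one effect size
#'
#' One draw of the per-site effect-size vector (length `num_traits`; 1
#' for univariate models). Exponential and gamma draws are multiplied by
#' an equiprobable random sign when the model's `random_sign` flag is set
#' (the default), since effect sizes must admit negative values.
#'
#' @param spec A validated [trait_model()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `num_traits`.
#' @export
draw_effect_size <- function(spec, seed = NULL) {
  spec <- validate_model(spec)
  .with_seed(seed, .draw_effect_matrix(spec, 1L)[1L, ])
}

# m draws as an m x num_traits matrix; one effect-size vector per site.
.draw_effect_matrix <- function(spec, m) {
  p <- spec$params
  if (m == 0L) return(matrix(0, nrow = 0, ncol = spec$num_traits))
  out <- switch(spec$name,
    normal = stats::rnorm(m, p$mean, sqrt(p$var)),
    fixed = rep(p$value, m),
    exponential = .signed(stats::rexp(m, rate = 1 / p$scale), p),
    gamma = .signed(stats::rgamma(m, shape = p$shape, scale = p$scale), p),
    t = p$mean + sqrt(p$var * (p$df - 2) / p$df) * stats::rt(m, df = p$df),
    mvn = MASS::mvrnorm(m, mu = p$mean, Sigma = p$cov)
  )
  matrix(out, nrow = m, ncol = spec$num_traits)
}

.signed <- function(x, p) {
  if (isFALSE(p$random_sign)) x
  else x * sample(c(-1, 1), length(x), replace = TRUE)
}

#' @export
print.trait_model <- function(x, ...) {
  ps <- vapply(x$params, function(v) {
    if (is.matrix(v)) sprintf("<%dx%d matrix>", nrow(v), ncol(v))
    else paste(format(v), collapse = ",")
  }, "")
  cat(sprintf("<trait_model> %s(%s), %d trait(s)\n", x$name,
              paste(names(ps), ps, sep = "=", collapse = ", "), x$num_traits))
  invisible(x)
}
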