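#' Build a simulation run configuration
#'
#' Collects and validates everything one simulation run needs, for use
#' by [run_simulation()] and by the command-line interface
#' (`inst/cli/argtrait_sim.R`). Exactly one of `num_causal` and
#' `causal_sites` drives causal-site placement.
#'
#' @param arg ARG input: an [arg_tables()] object, or a path to a
#'   `.trees` file or to a file in the TSV dialect of [read_arg()].
#' @param model A [trait_model()] or a specification string
#'   `"name:key=val,key=val"`, e.g. `"normal:mean=0,var=1"` (univariate
#'   models only; multivariate-normal models must be passed as objects).
#' @param num_causal Number of causal sites (default 1 when
#'   `causal_sites` is absent).
#' @param causal_sites Optional explicit causal sites: as accepted by
#'   [sim_trait()], or a path to a CSV with column `position` and
#'   optional `causal_allele`, `raw_beta`.
#' @param alpha Frequency-dependence exponent (default 0).
#' @param h2 Narrow-sense heritability in `(0, 1]` (default 0.3),
#'   scalar or per trait.
#' @param seed Non-negative integer master seed (default 0).
#' @param out Output directory (default `"."`).
#' @param format Output format; only `"csv"` is supported.
#' @return A validated `run_config` list.
#' @export
run_config <- function(arg, model, num_causal = NULL, causal_sites = NULL,
                       alpha = 0, h2 = 0.3, seed = 0, out = ".",
                       format = "csv") {
  if (!is.null(num_causal) && !is.null(causal_sites)) {
    abort("Supply either `num_causal` or `causal_sites`, not both.")
  }
  if (is.null(causal_sites)) {
    num_causal <- .check_count(num_causal %||% 1L, "num_causal")
  }
  seed <- .check_count(seed, "seed", positive = FALSE)
  format <- match.arg(format, "csv")
  structure(
    list(arg = arg, model = model, num_causal = num_causal,
         causal_sites = causal_sites, alpha = .check_scalar_num(alpha, "alpha"),
         h2 = h2, seed = seed, out = out, format = format),
    class = "run_config"
  )
}

#' Parse a trait-model specification string
#'
#' Turns `"name:key=val,key=val"` (the `--model` syntax of the
#' command-line interface) into a [trait_model()]. Values are numeric,
#' except `random_sign`, which accepts `true`/`false`. A bare `"name"`
#' uses the model's defaults where they exist.
#'
#' @param spec Specification string, e.g. `"normal:mean=0,var=1"` or
#'   `"fixed:value=0.05"`.
#' @return A validated [trait_model()].
#' @export
parse_model_string <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    abort("`spec` must be a single string like 'normal:mean=0,var=1'.")
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- parts[1]
  params <- list()
  if (length(parts) > 1 && nzchar(parts[2])) {
    for (kv in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      pair <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(pair) != 2L) {
        abort(sprintf("Malformed model parameter '%s'; expected key=value.", kv))
      }
      key <- trimws(pair[1])
      val <- trimws(pair[2])
      params[[key]] <- if (key == "random_sign") {
        tolower(val) %in% c("true", "t", "1", "yes")
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          abort(sprintf("Model parameter `%s` must be numeric; got '%s'.",
                        key, val))
        }
        num
      }
    }
  }
  do.call(trait_model, c(list(name = name), params))
}

#' Run a configured simulation and write its outputs
#'
#' Loads the ARG, runs [sim_phenotype()], and writes three files into
#' the output directory: `trait.csv` (causal sites, alleles, raw and
#' scaled effect sizes, allele frequencies), `phenotype.csv` (per
#' individual and trait: genetic value, environmental noise, phenotype)
#' and `run_log.json` (seed, parameters, package and R versions).
#' Re-running with the same configuration and seed produces
#' byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return The [sim_phenotype()] result, invisibly.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a `run_config` object (see `run_config()`).")
  }
  arg <- config$arg
  if (is.character(arg)) {
    if (!file.exists(arg)) {
      abort(sprintf("ARG input file not found: %s", arg))
    }
    arg <- if (grepl("\\.trees$", arg)) read_trees(arg) else read_arg(arg)
  }
  validate_arg(arg)

  model <- config$model
  if (is.character(model)) model <- parse_model_string(model)
  model <- validate_model(model)

  causal_sites <- config$causal_sites
  if (is.character(causal_sites)) {
    if (!file.exists(causal_sites)) {
      abort(sprintf("Causal-site file not found: %s", causal_sites))
    }
    # read as character so allele strings like "T" are never guessed
    # as logicals, then coerce the numeric columns
    causal_sites <- readr::read_csv(causal_sites, progress = FALSE,
                                    col_types = readr::cols(.default = "c"))
    for (nm in intersect(c("position", "raw_beta"), names(causal_sites))) {
      causal_sites[[nm]] <- as.numeric(causal_sites[[nm]])
    }
  }

  sim <- sim_phenotype(
    arg, model, h2 = config$h2,
    num_causal = config$num_causal %||% 1L,
    causal_sites = causal_sites, alpha = config$alpha, seed = config$seed
  )

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$trait, file.path(config$out, "trait.csv"),
                   progress = FALSE)
  readr::write_csv(sim$phenotype, file.path(config$out, "phenotype.csv"),
                   progress = FALSE)
  log <- list(
    seed = config$seed,
    model = list(name = model$name,
                 params = lapply(model$params, function(v) {
                   if (is.matrix(v)) as.vector(v) else v
                 }),
                 num_traits = model$num_traits),
    num_causal = config$num_causal,
    explicit_causal_sites = !is.null(config$causal_sites),
    alpha = config$alpha,
    h2 = config$h2,
    n_individuals = length(unique(sim$phenotype$individual_id)),
    versions = list(
      argtrait = as.character(utils::packageVersion("argtrait")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(log, file.path(config$out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}
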