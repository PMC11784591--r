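#' Read and write the plain-text ARG dialect
#'
#' The package's on-disk interchange format is a single TSV file with six
#' blocks, each introduced by a header line: `#sequence_length` (one
#' value), then `#nodes`, `#edges`, `#sites`, `#mutations` and
#' `#individuals`, each followed by a TSV table whose columns match the
#' corresponding [arg_tables()] fields (`individuals` carries `id` and a
#' comma-separated `nodes` list). Missing values are written as `NA`.
#' The format is deliberately plain text so fixtures and interchange with
#' other tools need no binary dependency.
#'
#' @param path File path.
#' @return `read_arg()` returns a validated [arg_tables()] object;
#'   `write_arg()` returns `path` invisibly. A write-then-read round trip
#'   reproduces the tables exactly.
#' @export
read_arg <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("ARG input file not found: %s", path))
  }
  lines <- readLines(path)
  heads <- grep("^#", lines)
  if (length(heads) == 0) {
    abort(sprintf("Parse error in %s: no block headers ('#nodes', ...) found.",
                  path))
  }
  blocks <- list()
  for (k in seq_along(heads)) {
    name <- sub("^#", "", lines[heads[k]])
    from <- heads[k] + 1L
    to <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    body <- lines[seq(from, to)]
    blocks[[name]] <- body[nzchar(body)]
  }
  need <- c("sequence_length", "nodes", "edges", "sites", "mutations",
            "individuals")
  missing <- setdiff(need, names(blocks))
  if (length(missing) > 0) {
    abort(sprintf("Parse error in %s: missing block(s) %s.", path,
                  paste0("#", missing, collapse = ", ")))
  }

  # Read as character and coerce through base R (strtod), which is
  # correctly rounded, so a write/read round trip is bit-exact.
  read_block <- function(name, col_types) {
    txt <- paste(blocks[[name]], collapse = "\n")
    df <- readr::read_tsv(I(txt),
                          col_types = readr::cols(.default = "c"),
                          na = "NA", progress = FALSE)
    col_types <- strsplit(col_types, "", fixed = TRUE)[[1]]
    for (j in seq_along(col_types)) {
      if (j > ncol(df)) break
      raw <- df[[j]]
      df[[j]] <- suppressWarnings(switch(col_types[[j]],
        i = as.integer(raw), d = as.numeric(raw),
        l = as.logical(raw), c = raw
      ))
      bad <- which(is.na(df[[j]]) & !is.na(raw))
      if (length(bad) > 0) {
        abort(sprintf(
          "Parse error in %s, block #%s, row %d: '%s' is not a valid %s.",
          path, name, bad[1], raw[bad[1]],
          c(i = "integer", d = "number", l = "logical",
            c = "string")[[col_types[[j]]]]))
      }
    }
    df
  }

  L <- suppressWarnings(as.numeric(blocks$sequence_length[1]))
  if (is.na(L)) {
    abort(sprintf("Parse error in %s: #sequence_length must be one number.",
                  path))
  }
  nodes <- read_block("nodes", "idli")
  edges <- read_block("edges", "ddii")
  sites <- read_block("sites", "idc")
  mutations <- read_block("mutations", "iiicid")
  ind_raw <- read_block("individuals", "ic")

  arg <- arg_tables(
    nodes = nodes, edges = edges, sites = sites, mutations = mutations,
    individuals = ind_raw["id"], sequence_length = L
  )

  # Cross-check the individuals' node lists against nodes$individual.
  listed <- lapply(ind_raw$nodes, function(s) {
    if (is.na(s) || !nzchar(s)) integer() else
      sort(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  })
  derived <- individual_nodes(arg)$nodes
  for (k in seq_along(listed)) {
    if (!identical(listed[[k]], sort(derived[[k]]))) {
      abort(sprintf(
        "ARG validation failed [individual-nodes]: individual %d lists nodes {%s} but nodes table assigns {%s}.",
        ind_raw$id[k], paste(listed[[k]], collapse = ","),
        paste(sort(derived[[k]]), collapse = ",")))
    }
  }
  arg
}

#' @rdname read_arg
#' @param arg An [arg_tables()] object to serialise.
#' @export
write_arg <- function(arg, path) {
  validate_arg(arg)
  tsv <- function(df) {
    # 17 significant digits so a write/read round trip is bit-exact.
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        v <- sprintf("%.17g", df[[nm]])
        v[is.na(df[[nm]])] <- NA_character_
        df[[nm]] <- v
      }
    }
    sub("\n$", "", readr::format_tsv(df, na = "NA"))
  }
  ind <- individual_nodes(arg)
  ind_df <- tibble(
    id = ind$individual_id,
    nodes = vapply(ind$nodes, function(v) paste(sort(v), collapse = ","), "")
  )
  out <- c(
    "#sequence_length",
    format(arg$sequence_length, digits = 17),
    "#nodes", tsv(arg$nodes),
    "#edges", tsv(arg$edges),
    "#sites", tsv(arg$sites),
    "#mutations", tsv(arg$mutations),
    "#individuals", tsv(ind_df)
  )
  writeLines(out, path)
  invisible(path)
}

#' Read a succinct tree-sequence (.trees) file
#'
#' Loads a tskit `.trees` file by converting its tables to the package's
#' TSV dialect with the Python tskit library (invoked through the
#' `python` executable on the PATH), then parsing with [read_arg()]. The
#' logical content — nodes, edges, sites, mutations, individuals — is
#' identical whichever dialect was read.
#'
#' @param path Path to a `.trees` file.
#' @param python Python executable to use (default `"python"`).
#' @return A validated [arg_tables()] object.
#' @export
read_trees <- function(path, python = "python") {
  if (!file.exists(path)) {
    abort(sprintf("ARG input file not found: %s", path))
  }
  script <- system.file("python", "trees_to_tsv.py", package = "argtrait")
  if (!nzchar(script)) {
    abort("Converter script not found; is the package installed correctly?")
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  status <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(path), shQuote(tmp)),
            stdout = NULL, stderr = TRUE)
  )
  if (!file.exists(tmp)) {
    abort(paste0(
      "Reading .trees requires the Python tskit library on the PATH ",
      "python; conversion failed:\n",
      paste(as.character(status), collapse = "\n")))
  }
  read_arg(tmp)
}
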