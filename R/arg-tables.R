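#' In-memory ARG tables
#'
#' `arg_tables()` bundles the five tables of a succinct tree sequence —
#' nodes, edges, sites, mutations and individuals — together with the
#' sequence length, into a validated `arg_tables` object. This is the
#' substrate every simulation stage queries; it mirrors the tskit table
#' layout (0-based contiguous ids, half-open `[left, right)` edge
#' intervals, real-valued site positions).
#'
#' @param nodes Data frame with columns `id` (0-based integer), `time`
#'   (non-negative, generations), `is_sample` (logical) and `individual`
#'   (individual id or `NA` for nodes not belonging to an individual).
#' @param edges Data frame with columns `left`, `right` (genome
#'   coordinates, half-open interval), `parent`, `child` (node ids).
#' @param sites Data frame with columns `id`, `position` (in
#'   `[0, sequence_length)`, strictly increasing with id) and
#'   `ancestral_state` (allele string).
#' @param mutations Data frame with columns `id`, `site`, `node`,
#'   `derived_state`, `parent` (mutation id of the next mutation towards
#'   the root at the same site, or `NA`) and `time` (or `NA` if unknown).
#' @param individuals Data frame with column `id`. Node membership is
#'   carried by `nodes$individual`.
#' @param sequence_length Positive genome length in base pairs.
#' @param validate Run [validate_arg()] on the result (default `TRUE`).
#'
#' @return An `arg_tables` object: a list of tibbles plus
#'   `sequence_length`.
#' @seealso [read_arg()], [tree_at()], [resolve_states()]
#' @export
arg_tables <- function(nodes, edges, sites = NULL, mutations = NULL,
                       individuals = NULL, sequence_length, validate = TRUE) {
  empty <- function(...) tibble::tibble(...)
  sites <- sites %||% empty(id = integer(), position = double(),
                            ancestral_state = character())
  mutations <- mutations %||% empty(id = integer(), site = integer(),
                                    node = integer(),
                                    derived_state = character(),
                                    parent = integer(), time = double())
  individuals <- individuals %||% empty(id = integer())

  x <- structure(
    list(
      nodes = .coerce_cols(nodes, list(id = "integer", time = "double",
                                       is_sample = "logical",
                                       individual = "integer")),
      edges = .coerce_cols(edges, list(left = "double", right = "double",
                                       parent = "integer", child = "integer")),
      sites = .coerce_cols(sites, list(id = "integer", position = "double",
                                       ancestral_state = "character")),
      mutations = .coerce_cols(mutations, list(id = "integer", site = "integer",
                                               node = "integer",
                                               derived_state = "character",
                                               parent = "integer",
                                               time = "double")),
      individuals = .coerce_cols(individuals, list(id = "integer")),
      sequence_length = .check_scalar_num(sequence_length, "sequence_length")
    ),
    class = "arg_tables"
  )
  if (validate) validate_arg(x) else x
}

.coerce_cols <- function(df, spec) {
  if (!is.data.frame(df)) {
    abort("Each ARG table must be a data frame.")
  }
  missing <- setdiff(names(spec), names(df))
  if (length(missing) > 0) {
    abort(sprintf("ARG table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[names(spec)]
  for (nm in names(spec)) {
    df[[nm]] <- switch(spec[[nm]],
      integer = as.integer(df[[nm]]),
      double = as.double(df[[nm]]),
      logical = as.logical(df[[nm]]),
      character = as.character(df[[nm]])
    )
  }
  df
}

#' Validate ARG tables
#'
#' Checks the structural invariants of an [arg_tables()] object: ids are
#' 0-based and contiguous, every edge's parent is strictly older than its
#' child, no two edges for the same child overlap, site positions are
#' strictly increasing and inside the genome, mutations reference existing
#' sites/nodes and their `parent` links stay at the same site, and node
#' individual ids exist. The first violated rule is reported by name.
#'
#' @param arg An `arg_tables` object.
#' @return `arg` invisibly-validated (returned unchanged) or an error
#'   naming the violated rule.
#' @export
validate_arg <- function(arg) {
  if (!inherits(arg, "arg_tables")) {
    abort("`arg` must be an `arg_tables` object (see `arg_tables()`).")
  }
  nd <- arg$nodes; ed <- arg$edges; st <- arg$sites
  mu <- arg$mutations; ind <- arg$individuals
  L <- arg$sequence_length

  fail <- function(rule, ...) {
    abort(sprintf("ARG validation failed [%s]: %s", rule, sprintf(...)))
  }
  check_ids <- function(ids, what) {
    if (anyNA(ids) || (length(ids) > 0 && !identical(sort(ids),
                                                     seq_len(length(ids)) - 1L))) {
      fail("contiguous-ids", "%s ids must be 0..%d with no gaps.",
           what, length(ids) - 1L)
    }
  }
  if (nrow(nd) == 0) fail("nonempty-nodes", "at least one node is required.")
  if (!is.finite(L) || L <= 0) fail("sequence-length",
                                    "sequence_length must be positive.")
  check_ids(nd$id, "node")
  check_ids(st$id, "site")
  check_ids(mu$id, "mutation")
  check_ids(ind$id, "individual")
  if (any(is.na(nd$time)) || any(nd$time < 0)) {
    fail("node-time", "node times must be non-negative.")
  }

  if (nrow(ed) > 0) {
    if (any(!ed$parent %in% nd$id) || any(!ed$child %in% nd$id)) {
      fail("edge-node-ref", "edge parent/child must be existing node ids.")
    }
    tm <- nd$time[match(ed$parent, nd$id)] - nd$time[match(ed$child, nd$id)]
    if (any(tm <= 0)) {
      fail("edge-time-order",
           "edge row %d: parent must be strictly older than child.",
           which(tm <= 0)[1])
    }
    if (any(ed$left < 0) || any(ed$right > L) || any(ed$left >= ed$right)) {
      fail("edge-interval", "edge intervals must satisfy 0 <= left < right <= L.")
    }
    o <- order(ed$child, ed$left)
    ch <- ed$child[o]; lf <- ed$left[o]; rt <- ed$right[o]
    k <- length(o)
    if (k > 1) {
      bad <- ch[-1] == ch[-k] & lf[-1] < rt[-k]
      if (any(bad)) {
        fail("edge-child-overlap",
             "edges for child %d have overlapping intervals.",
             ch[-1][bad][1])
      }
    }
  }

  if (nrow(st) > 0) {
    pos <- st$position[order(st$id)]
    if (any(pos < 0) || any(pos >= L)) {
      fail("site-position", "site positions must lie in [0, sequence_length).")
    }
    if (nrow(st) > 1 && any(diff(pos) <= 0)) {
      fail("site-order", "site positions must be strictly increasing with id.")
    }
  }

  if (nrow(mu) > 0) {
    if (any(!mu$site %in% st$id)) {
      fail("mutation-site-ref", "mutation site must be an existing site id.")
    }
    if (any(!mu$node %in% nd$id)) {
      fail("mutation-node-ref", "mutation node must be an existing node id.")
    }
    has_par <- !is.na(mu$parent)
    if (any(has_par)) {
      if (any(!mu$parent[has_par] %in% mu$id)) {
        fail("mutation-parent-ref", "parent_mutation must be an existing mutation id.")
      }
      same_site <- mu$site[match(mu$parent[has_par], mu$id)] == mu$site[has_par]
      if (any(!same_site)) {
        fail("mutation-parent-site",
             "a mutation's parent mutation must be at the same site.")
      }
      if (any(mu$parent[has_par] == mu$id[has_par])) {
        fail("mutation-parent-self", "a mutation cannot be its own parent.")
      }
    }
  }

  has_ind <- !is.na(nd$individual)
  if (any(has_ind) && any(!nd$individual[has_ind] %in% ind$id)) {
    fail("node-individual-ref", "node individual must be an existing individual id.")
  }
  arg
}

#' @export
print.arg_tables <- function(x, ...) {
  cat(sprintf(
    "<arg_tables> sequence length %g bp\n  %d nodes (%d samples), %d edges, %d sites, %d mutations, %d individuals\n",
    x$sequence_length, nrow(x$nodes), sum(x$nodes$is_sample), nrow(x$edges),
    nrow(x$sites), nrow(x$mutations), nrow(x$individuals)
  ))
  invisible(x)
}

#' Nodes belonging to each individual
#'
#' @param arg An `arg_tables` object.
#' @return A tibble with one row per individual: `individual_id` and a
#'   list-column `nodes` of node ids (possibly empty).
#' @export
individual_nodes <- function(arg) {
  validate_arg(arg)
  nd <- arg$nodes
  tibble(
    individual_id = arg$individuals$id,
    nodes = lapply(arg$individuals$id, function(i) {
      nd$id[!is.na(nd$individual) & nd$individual == i]
    })
  )
}

.n_nodes <- function(arg) nrow(arg$nodes)

.site_row <- function(arg, site) {
  i <- which(arg$sites$id == site)
  if (length(i) != 1L) {
    abort(sprintf("Site %s does not exist in this ARG.", format(site)))
  }
  arg$sites[i, ]
}
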