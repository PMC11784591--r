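#' Extract the local tree at a genome position
#'
#' An ARG is a sequence of correlated genealogical trees along the genome;
#' between two consecutive edge breakpoints the tree is constant.
#' `tree_at()` returns the local tree whose interval contains `position`,
#' as a parent array over all nodes of the ARG. Nodes not covered by any
#' edge at that position (roots and isolated nodes) have parent `NA`.
#'
#' @param arg An [arg_tables()] object.
#' @param position Genome coordinate in `[0, sequence_length)`.
#' @return A `local_tree`: list with `interval` (the `[left, right)`
#'   breakpoint interval), `parent` (integer vector indexed by
#'   `node id + 1`, `NA` where the node has no parent) and `n_nodes`.
#' @export
tree_at <- function(arg, position) {
  validate_arg(arg)
  .tree_at(arg, position)
}

# As tree_at(), without re-validating the tables (internal hot path).
.tree_at <- function(arg, position) {
  position <- .check_scalar_num(position, "position")
  if (position < 0 || position >= arg$sequence_length) {
    abort(sprintf("`position` must lie in [0, %g); got %g.",
                  arg$sequence_length, position))
  }
  ed <- arg$edges
  n <- .n_nodes(arg)
  parent <- rep(NA_integer_, n)
  if (nrow(ed) > 0) {
    act <- ed$left <= position & position < ed$right
    parent[ed$child[act] + 1L] <- ed$parent[act]
  }
  bp <- sort(unique(c(0, ed$left, ed$right, arg$sequence_length)))
  structure(
    list(
      interval = c(max(bp[bp <= position]), min(bp[bp > position])),
      parent = parent,
      n_nodes = n
    ),
    class = "local_tree"
  )
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("<local_tree> interval [%g, %g), %d nodes, %d root(s)\n",
              x$interval[1], x$interval[2], x$n_nodes, sum(is.na(x$parent))))
  invisible(x)
}

# Children adjacency: list of length n_nodes, entry i = child node ids of
# node id i-1.
.children_of <- function(tree) {
  p <- tree$parent
  has <- !is.na(p)
  unname(split(which(has) - 1L,
               factor(p[has], levels = seq_len(tree$n_nodes) - 1L)))
}

# Effective own-mutation state per node at one site: when several mutations
# sit on the same node, the most recent one wins. Ordering uses
# parent-mutation links when they identify a unique chain tail, otherwise
# mutation times (smaller time = more recent); inputs with neither are
# rejected as ambiguous.
.node_mutation_states <- function(arg, site) {
  mu <- arg$mutations[arg$mutations$site == site, , drop = FALSE]
  n <- .n_nodes(arg)
  out <- rep(NA_character_, n)
  if (nrow(mu) == 0) return(out)
  for (nd in unique(mu$node)) {
    g <- mu[mu$node == nd, , drop = FALSE]
    if (nrow(g) == 1L) {
      out[nd + 1L] <- g$derived_state
      next
    }
    tails <- setdiff(g$id, g$parent)
    if (length(tails) == 1L) {
      out[nd + 1L] <- g$derived_state[g$id == tails]
    } else if (!anyNA(g$time) && sum(g$time == min(g$time)) == 1L) {
      out[nd + 1L] <- g$derived_state[which.min(g$time)]
    } else {
      abort(sprintf(
        "ARG validation failed [mutation-order]: %d mutations on node %d at site %d cannot be ordered (no parent links, no usable times).",
        nrow(g), nd, site))
    }
  }
  out
}

#' Resolve allele states at a site
#'
#' Assigns every node of the ARG its allele at one site: the derived state
#' of the most recent mutation on its path to the root of the local tree
#' (including mutations on the node itself), or the site's ancestral state
#' if no such mutation exists. Back-mutations are honoured — a lineage
#' reverted to an earlier allele propagates that allele to its
#' descendants. Nodes outside the local tree keep the ancestral state
#' unless they carry a mutation themselves.
#'
#' @param arg An [arg_tables()] object.
#' @param site Site id.
#' @return A tibble with columns `node` and `state` covering every node.
#' @export
resolve_states <- function(arg, site) {
  validate_arg(arg)
  srow <- .site_row(arg, site)
  tree <- tree_at(arg, srow$position)
  tibble(node = seq_len(.n_nodes(arg)) - 1L,
         state = .resolve_states_vec(arg, site, tree))
}

# Vector version (indexed by node id + 1); `tree` and `children` may be
# precomputed and shared across the sites of one local tree. States are
# filled by preorder walks from each mutation, pruning at nested
# mutations, so the cost is proportional to the mutated subtrees rather
# than the whole tree.
.resolve_states_vec <- function(arg, site, tree = NULL, children = NULL) {
  srow <- .site_row(arg, site)
  tree <- tree %||% .tree_at(arg, srow$position)
  children <- children %||% .children_of(tree)
  ms <- .node_mutation_states(arg, site)
  n <- tree$n_nodes
  st <- rep(srow$ancestral_state, n)
  entries <- which(!is.na(ms))
  stack <- integer(n)
  for (e0 in entries) {
    state <- ms[e0]
    top <- 1L
    stack[1L] <- e0
    while (top > 0L) {
      i <- stack[top]
      top <- top - 1L
      st[i] <- state
      kids <- children[[i]]
      if (length(kids)) {
        ki <- kids + 1L
        ki <- ki[is.na(ms[ki])] # halt at nested mutations
        nk <- length(ki)
        if (nk) {
          stack[(top + 1L):(top + nk)] <- ki
          top <- top + nk
        }
      }
    }
  }
  st
}

# Shared per-position cache of local trees and children adjacencies:
# returns a lookup closure. Trees are piecewise-constant between edge
# breakpoints, so each distinct tree is built once.
.tree_ctx <- function(arg) {
  cache <- new.env(parent = emptyenv())
  breakpoints <- sort(unique(c(0, arg$edges$left, arg$edges$right)))
  function(pos) {
    key <- as.character(findInterval(pos, breakpoints))
    got <- cache[[key]]
    if (is.null(got)) {
      tr <- .tree_at(arg, pos)
      got <- list(tree = tr, children = .children_of(tr))
      cache[[key]] <- got
    }
    got
  }
}

#' Allele frequency among sample nodes
#'
#' The frequency `p` of an allele at a site, computed over sample nodes
#' only: the fraction of sample genomes whose resolved state equals
#' `allele`. This is the `p` entering the frequency-dependent effect-size
#' scaling `(2p(1-p))^(alpha/2)`.
#'
#' @param arg An [arg_tables()] object with at least one sample node.
#' @param site Site id.
#' @param allele Allele string.
#' @return Frequency in `[0, 1]`.
#' @export
allele_frequency <- function(arg, site, allele) {
  validate_arg(arg)
  samp <- arg$nodes$is_sample
  if (!any(samp)) {
    abort("Allele frequency is undefined: the ARG has no sample nodes.")
  }
  st <- .resolve_states_vec(arg, site)
  mean(st[arg$nodes$id[samp] + 1L] == allele)
}

# Allele frequency spectrum over sample nodes at one site.
.sample_state_freqs <- function(arg, site, tree = NULL, children = NULL) {
  st <- .resolve_states_vec(arg, site, tree, children)
  samp <- st[arg$nodes$id[arg$nodes$is_sample] + 1L]
  tab <- table(samp)
  tibble(allele = names(tab), p = as.numeric(tab) / length(samp))
}
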