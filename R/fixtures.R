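#' Minimal worked-example ARG with a back-mutation
#'
#' A hand-built single-tree ARG of three diploid individuals: six sample
#' leaves `a`..`f` (node ids 0..5; individual 0 owns `a` and `b`,
#' individual 1 owns `c` and `d`, individual 2 owns `e` and `f`), five
#' internal nodes `g`..`k` (ids 6..10, not associated with any
#' individual), and one site (position 50, ancestral state `A`) with two
#' mutations: a mutation to `T` on the branch above internal node `i`
#' (id 9) and a back-mutation to `A` on the branch above leaf `e`
#' (id 4). Resolving states therefore gives `T` to every node below `i`
#' — `i` itself, `h`, `j`, and leaves `c`, `d`, `f` — except `e`, whose
#' back-mutation restores `A`; the sample frequency of `T` is 0.5.
#'
#' With the causal allele `T` and a fixed effect size of 0.05, every
#' node below the causal mutation has genetic value 0.05 except `e`
#' (value 0), so the individual genetic values are 0, 0.1 and 0.05.
#'
#' @return A validated [arg_tables()] object.
#' @export
make_example_arg <- function() {
  # leaves a..f = 0..5; internal g = 6 (a,b), h = 7 (c,d), j = 8 (e,f),
  # i = 9 (h,j), root k = 10 (g,i)
  nodes <- tibble(
    id = 0:10,
    time = c(rep(0, 6), 1, 1, 1.2, 2, 3),
    is_sample = c(rep(TRUE, 6), rep(FALSE, 5)),
    individual = c(0L, 0L, 1L, 1L, 2L, 2L, rep(NA_integer_, 5))
  )
  edges <- tibble(
    left = 0, right = 100,
    parent = c(6L, 6L, 7L, 7L, 8L, 8L, 9L, 9L, 10L, 10L),
    child = c(0L, 1L, 2L, 3L, 4L, 5L, 7L, 8L, 6L, 9L)
  )
  sites <- tibble(id = 0L, position = 50, ancestral_state = "A")
  mutations <- tibble(
    id = 0:1,
    site = 0L,
    node = c(9L, 4L),
    derived_state = c("T", "A"),
    parent = c(NA_integer_, 0L),
    time = c(2.5, 0.6)
  )
  individuals <- tibble(id = 0:2)
  arg_tables(nodes, edges, sites, mutations, individuals,
             sequence_length = 100)
}

#' Random ARG generator
#'
#' Generates a random multi-tree ARG for testing and validation: each of
#' `n_trees` equal-length genome segments gets an independent random
#' coalescent topology over the shared sample nodes (fresh internal
#' nodes per tree, exponential waiting times between coalescences);
#' sites are placed uniformly along the genome, each with one mutation
#' on a random non-root branch of its local tree; with probability
#' `stacked_mutation_rate` a site receives a second mutation — on a
#' descendant branch when one exists (a stacked or back-mutation, with
#' the `parent` link set; half the time it reverts to the ancestral
#' state), otherwise on an independent branch (a multiallelic site).
#' Sample nodes are paired into diploid individuals (a trailing haploid
#' individual if `n_samples` is odd).
#'
#' @param n_samples Number of sample nodes (>= 2).
#' @param n_sites Number of sites (>= 0).
#' @param n_trees Number of local trees (default 1; `n_trees - 1`
#'   recombination breakpoints).
#' @param stacked_mutation_rate Probability in `[0, 1]` that a site gets
#'   a second mutation (default 0: exactly one mutation per site).
#' @param seed Optional integer seed; the output is deterministic per
#'   seed.
#' @return A validated [arg_tables()] object with
#'   `sequence_length = 100 * n_trees`.
#' @export
make_random_arg <- function(n_samples, n_sites, n_trees = 1,
                            stacked_mutation_rate = 0, seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples")
  n_sites <- .check_count(n_sites, "n_sites", positive = FALSE)
  n_trees <- .check_count(n_trees, "n_trees")
  if (n_samples < 2) {
    abort("`n_samples` must be at least 2 to build a coalescent tree.")
  }
  if (!is.numeric(stacked_mutation_rate) || stacked_mutation_rate < 0 ||
      stacked_mutation_rate > 1) {
    abort("`stacked_mutation_rate` must lie in [0, 1].")
  }
  .with_seed(seed, .build_random_arg(n_samples, n_sites, n_trees,
                                     stacked_mutation_rate))
}

.build_random_arg <- function(n_samples, n_sites, n_trees, stacked_rate) {
  L <- 100 * n_trees
  n_nodes <- n_samples + (n_samples - 1L) * n_trees
  node_time <- numeric(n_nodes)
  n_edges <- 2L * (n_samples - 1L) * n_trees
  e_left <- numeric(n_edges); e_right <- numeric(n_edges)
  e_parent <- integer(n_edges); e_child <- integer(n_edges)
  tree_parent <- vector("list", n_trees) # per-tree parent lookup, node id + 1

  next_id <- n_samples
  eidx <- 0L
  for (t in seq_len(n_trees)) {
    left <- 100 * (t - 1)
    right <- 100 * t
    active <- seq_len(n_samples) - 1L
    na <- n_samples
    tm <- 0
    parent_map <- rep(NA_integer_, n_nodes)
    while (na > 1L) {
      idx <- sample.int(na, 2L)
      pair <- active[idx]
      tm <- tm + stats::rexp(1) / na
      new_node <- next_id
      next_id <- next_id + 1L
      node_time[new_node + 1L] <- tm
      e_left[eidx + 1:2] <- left
      e_right[eidx + 1:2] <- right
      e_parent[eidx + 1:2] <- new_node
      e_child[eidx + 1:2] <- sort(pair)
      eidx <- eidx + 2L
      parent_map[pair + 1L] <- new_node
      # replace one coalesced lineage with the parent, drop the other
      active[idx[1]] <- new_node
      active[idx[2]] <- active[na]
      na <- na - 1L
    }
    tree_parent[[t]] <- parent_map
  }
  edges <- tibble(left = e_left, right = e_right, parent = e_parent,
                  child = e_child)

  sites <- tibble(
    id = seq_len(n_sites) - 1L,
    position = sort(stats::runif(n_sites, 0, L)),
    ancestral_state = rep("A", n_sites)
  )
  derived_pool <- c("C", "G", "T")

  # children adjacency per tree, built lazily for descendant lookups
  tree_children <- vector("list", n_trees)
  children_of_tree <- function(t) {
    if (is.null(tree_children[[t]])) {
      pm <- tree_parent[[t]]
      has <- !is.na(pm)
      tree_children[[t]] <<- unname(split(which(has) - 1L,
                                          factor(pm[has],
                                                 levels = 0:(n_nodes - 1L))))
    }
    tree_children[[t]]
  }
  descendants_of <- function(t, node) {
    ch <- children_of_tree(t)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      kids <- ch[[x + 1L]]
      out <- c(out, kids)
      stack <- c(stack, kids)
    }
    out
  }

  m_node <- integer(0); m_site <- integer(0); m_state <- character(0)
  m_parent <- integer(0); m_time <- numeric(0)
  for (s in seq_len(n_sites)) {
    t <- min(floor(sites$position[s] / 100) + 1, n_trees)
    pm <- tree_parent[[t]]
    candidates <- which(!is.na(pm)) - 1L # non-root nodes of this tree
    nd1 <- .sample_vec(candidates, 1L)
    mid1 <- length(m_node)
    m_node <- c(m_node, nd1); m_site <- c(m_site, s - 1L)
    m_state <- c(m_state, .sample_vec(derived_pool, 1L))
    m_parent <- c(m_parent, NA_integer_)
    m_time <- c(m_time, (node_time[nd1 + 1L] + node_time[pm[nd1 + 1L] + 1L]) / 2)

    if (stats::runif(1) < stacked_rate) {
      desc <- intersect(descendants_of(t, nd1), candidates)
      if (length(desc) > 0) {
        # stacked (possibly back-) mutation on a descendant branch
        nd2 <- .sample_vec(desc, 1L)
        st2 <- if (stats::runif(1) < 0.5) "A" else
          .sample_vec(setdiff(derived_pool, m_state[mid1 + 1L]), 1L)
        par2 <- mid1
      } else {
        # no descendant branch: make the site multiallelic instead
        nd2 <- .sample_vec(candidates[candidates != nd1], 1L)
        st2 <- .sample_vec(setdiff(derived_pool, m_state[mid1 + 1L]), 1L)
        par2 <- NA_integer_
      }
      m_node <- c(m_node, nd2); m_site <- c(m_site, s - 1L)
      m_state <- c(m_state, st2); m_parent <- c(m_parent, par2)
      m_time <- c(m_time, (node_time[nd2 + 1L] + node_time[pm[nd2 + 1L] + 1L]) / 2)
    }
  }
  mutations <- if (length(m_node)) {
    tibble(id = seq_along(m_node) - 1L, site = m_site, node = m_node,
           derived_state = m_state, parent = m_parent, time = m_time)
  } else NULL

  n_ind <- ceiling(n_samples / 2)
  node_ind <- rep(seq_len(n_ind) - 1L, each = 2L)[seq_len(n_samples)]
  nodes <- tibble(
    id = seq_len(n_nodes) - 1L,
    time = node_time,
    is_sample = c(rep(TRUE, n_samples), rep(FALSE, n_nodes - n_samples)),
    individual = c(node_ind, rep(NA_integer_, n_nodes - n_samples))
  )
  arg_tables(nodes, edges, sites, mutations,
             individuals = tibble(id = seq_len(n_ind) - 1L),
             sequence_length = L)
}
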