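# Independent brute-force oracles, deliberately implemented differently
# from the package: allele states by an upward per-node root-path walk
# (the package propagates states downward), and genetic values from the
# full causal genotype matrix (the package traverses causal subtrees).

# Allele state of every node by walking each node's path to the root of
# the local tree and taking the first mutation encountered.
oracle_states <- function(arg, site) {
  srow <- arg$sites[arg$sites$id == site, ]
  pos <- srow$position
  act <- arg$edges$left <= pos & pos < arg$edges$right
  parent_of <- function(n) {
    i <- which(act & arg$edges$child == n)
    if (length(i) == 1L) arg$edges$parent[i] else NA_integer_
  }
  mu <- arg$mutations[arg$mutations$site == site, , drop = FALSE]
  own_state <- function(n) {
    g <- mu[mu$node == n, , drop = FALSE]
    if (nrow(g) == 0L) return(NA_character_)
    if (nrow(g) == 1L) return(g$derived_state)
    tails <- setdiff(g$id, g$parent)
    if (length(tails) == 1L) return(g$derived_state[g$id == tails])
    g$derived_state[which.min(g$time)]
  }
  vapply(arg$nodes$id, function(n) {
    x <- n
    repeat {
      s <- own_state(x)
      if (!is.na(s)) return(s)
      p <- parent_of(x)
      if (is.na(p)) return(srow$ancestral_state)
      x <- p
    }
  }, character(1))
}

# Frequency of `allele` among sample nodes, from the state oracle.
oracle_freq <- function(arg, site, allele) {
  st <- oracle_states(arg, site)
  mean(st[arg$nodes$id[arg$nodes$is_sample] + 1L] == allele)
}

# Per-individual genetic values from the causal genotype dosage:
# G_ind = sum over sites of beta_s * (number of the individual's nodes
# carrying the causal allele at site s).
oracle_genetic_values <- function(arg, traits) {
  inds <- arg$individuals$id
  out <- list()
  for (tid in sort(unique(traits$trait_id))) {
    tt <- traits[traits$trait_id == tid, , drop = FALSE]
    g <- stats::setNames(rep(0, length(inds)), inds)
    for (i in seq_len(nrow(tt))) {
      st <- oracle_states(arg, tt$site_id[i])
      for (ind in inds) {
        nodes <- arg$nodes$id[!is.na(arg$nodes$individual) &
                                arg$nodes$individual == ind]
        dosage <- sum(st[nodes + 1L] == tt$causal_allele[i])
        g[as.character(ind)] <- g[as.character(ind)] +
          tt$scaled_beta[i] * dosage
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      individual_id = inds, trait_id = tid, genetic_value = unname(g)
    )
  }
  dplyr::bind_rows(out)
}

# A small hand-built single-tree ARG with a triallelic site: ancestral A,
# derived T (two carriers) and G (one carrier) among 4 samples.
triallelic_arg <- function() {
  nodes <- tibble::tibble(
    id = 0:6,
    time = c(0, 0, 0, 0, 1, 1, 2),
    is_sample = c(rep(TRUE, 4), rep(FALSE, 3)),
    individual = c(0L, 0L, 1L, 1L, NA, NA, NA)
  )
  edges <- tibble::tibble(
    left = 0, right = 100,
    parent = c(4L, 4L, 5L, 5L, 6L, 6L),
    child = c(0L, 1L, 2L, 3L, 4L, 5L)
  )
  sites <- tibble::tibble(id = 0L, position = 10, ancestral_state = "A")
  mutations <- tibble::tibble(
    id = 0:1, site = 0L, node = c(4L, 2L),
    derived_state = c("T", "G"),
    parent = NA_integer_, time = c(1.5, 0.5)
  )
  arg_tables(nodes, edges, sites, mutations,
             individuals = tibble::tibble(id = 0:1), sequence_length = 100)
}

# A two-tree ARG with one recombination breakpoint at position 50: the
# cherry structure over 4 samples differs between the two halves.
two_tree_arg <- function() {
  nodes <- tibble::tibble(
    id = 0:6,
    time = c(0, 0, 0, 0, 1, 1, 2),
    is_sample = c(rep(TRUE, 4), rep(FALSE, 3)),
    individual = c(0L, 0L, 1L, 1L, NA, NA, NA)
  )
  edges <- tibble::tibble(
    left   = c(0,  0, 50, 50,  0,  0, 50, 50,  0,  0),
    right  = c(50, 50, 100, 100, 50, 50, 100, 100, 100, 100),
    parent = c(4L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L, 6L),
    child  = c(0L, 1L, 0L, 2L, 2L, 3L, 1L, 3L, 4L, 5L)
  )
  sites <- tibble::tibble(id = 0:1, position = c(25, 75),
                          ancestral_state = c("A", "A"))
  mutations <- tibble::tibble(
    id = 0:1, site = 0:1, node = c(4L, 4L),
    derived_state = c("T", "T"), parent = NA_integer_, time = c(1.5, 1.5)
  )
  arg_tables(nodes, edges, sites, mutations,
             individuals = tibble::tibble(id = 0:1), sequence_length = 100)
}
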