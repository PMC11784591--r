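#' Per-node genetic values at one causal site
#'
#' Every node of the local tree whose allele at the site equals the
#' causal allele receives the (scaled) effect size; every other node
#' receives 0. The assignment is made by subtree traversal, not by
#' decoding genotypes: a preorder walk starts at each mutation to the
#' causal allele (and at the local roots when the causal allele is the
#' ancestral state) and descends, halting at any node carrying its own
#' mutation at the site — such a node either starts its own walk (same
#' allele) or is pruned together with its subtree (different allele, e.g.
#' a back-mutation). Cost is proportional to the causal subtrees, not to
#' the whole tree.
#'
#' @param arg An [arg_tables()] object.
#' @param site Site id.
#' @param causal_allele Allele whose carriers receive the effect.
#' @param scaled_beta Effect size assigned to each carrier node.
#' @return A tibble with columns `node` and `value` covering every node.
#' @export
node_values_for_site <- function(arg, site, causal_allele, scaled_beta) {
  validate_arg(arg)
  tibble(node = seq_len(.n_nodes(arg)) - 1L,
         value = .node_values_vec(arg, site, causal_allele, scaled_beta))
}

# Vector version; `tree` and `children` may be precomputed and shared
# across the sites of one local tree.
.node_values_vec <- function(arg, site, causal_allele, scaled_beta,
                             tree = NULL, children = NULL) {
  srow <- .site_row(arg, site)
  tree <- tree %||% .tree_at(arg, srow$position)
  children <- children %||% .children_of(tree)
  ms <- .node_mutation_states(arg, site)
  n <- tree$n_nodes
  val <- numeric(n)

  entries <- which(!is.na(ms) & ms == causal_allele)
  if (identical(causal_allele, srow$ancestral_state)) {
    # Local roots (and isolated nodes) without their own mutation carry
    # the ancestral state.
    entries <- c(entries, which(is.na(tree$parent) & is.na(ms)))
  }
  stack <- integer(n)
  for (e0 in entries) {
    top <- 1L
    stack[1L] <- e0
    while (top > 0L) {
      i <- stack[top]
      top <- top - 1L
      val[i] <- scaled_beta
      kids <- children[[i]]
      if (length(kids)) {
        # Descend only into mutation-free children: a child with its own
        # mutation is either pruned (different allele) or the start of
        # its own walk (same allele).
        ki <- kids + 1L
        ki <- ki[is.na(ms[ki])]
        nk <- length(ki)
        if (nk) {
          stack[(top + 1L):(top + nk)] <- ki
          top <- top + nk
        }
      }
    }
  }
  val
}

#' Aggregate genetic values per individual
#'
#' The second stage of the simulator: for each trait, per-node genetic
#' values are computed at every causal site of the trait table and
#' summed (sites in ascending id order, so results are bit-reproducible),
#' then each individual's genetic value G is the sum over the nodes
#' assigned to it — the additive model. Individuals with no carrier
#' nodes (or no nodes at all) are listed with G = 0. Nodes that belong
#' to individuals but are not samples (pedigree-embedded ARGs) do
#' contribute.
#'
#' @param arg An [arg_tables()] object.
#' @param traits A trait table as returned by [sim_trait()] (columns
#'   `site_id`, `causal_allele`, `scaled_beta`, `trait_id` are used).
#' @return A tibble with columns `individual_id`, `trait_id`,
#'   `genetic_value`, one row per individual and trait, ordered by trait
#'   then individual.
#' @export
genetic_values <- function(arg, traits) {
  validate_arg(arg)
  need <- c("site_id", "causal_allele", "scaled_beta", "trait_id")
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0) {
    abort(sprintf("`traits` is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(traits) > 0) {
    unknown <- setdiff(unique(traits$site_id), arg$sites$id)
    if (length(unknown) > 0) {
      abort(sprintf("Trait table references unknown site id(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    for (i in seq_len(nrow(traits))) {
      site_alleles <- c(
        .site_row(arg, traits$site_id[i])$ancestral_state,
        arg$mutations$derived_state[arg$mutations$site == traits$site_id[i]]
      )
      if (!traits$causal_allele[i] %in% site_alleles) {
        abort(sprintf(
          "Trait table row %d: allele '%s' never occurs at site %d.",
          i, traits$causal_allele[i], traits$site_id[i]))
      }
    }
  }

  n <- .n_nodes(arg)
  trait_ids <- if (nrow(traits) > 0) sort(unique(traits$trait_id)) else 0L
  node_ind <- arg$nodes$individual
  has_ind <- !is.na(node_ind)
  inds <- arg$individuals$id

  # Local trees are piecewise-constant: build each one once and share it
  # across all causal sites falling in its interval.
  tree_for <- .tree_ctx(arg)

  res <- lapply(trait_ids, function(tid) {
    tt <- traits[traits$trait_id == tid, , drop = FALSE]
    tt <- tt[order(tt$site_id), , drop = FALSE]
    # Accumulate G_ind = sum over sites of beta * (carrier-node count),
    # sites in ascending id order: one multiply and one add per site, so
    # results are bit-reproducible and exactly the genotype-dosage sum.
    g <- numeric(length(inds))
    names(g) <- inds
    for (i in seq_len(nrow(tt))) {
      pos <- .site_row(arg, tt$site_id[i])$position
      tc <- tree_for(pos)
      carrier <- .node_values_vec(arg, tt$site_id[i], tt$causal_allele[i],
                                  1, tree = tc$tree, children = tc$children)
      if (any(has_ind)) {
        dosage <- rowsum(carrier[which(has_ind)], group = node_ind[has_ind])
        g[rownames(dosage)] <- g[rownames(dosage)] +
          tt$scaled_beta[i] * dosage[, 1]
      }
    }
    tibble(individual_id = inds, trait_id = tid, genetic_value = unname(g))
  })
  dplyr::bind_rows(res)
}
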