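test_that("arg_tables validation catches broken invariants by name", {
  arg <- make_example_arg()
  expect_s3_class(validate_arg(arg), "arg_tables")

  bad <- arg
  bad$edges$parent[1] <- 0L # parent not older than child
  bad$edges$child[1] <- 6L
  expect_error(validate_arg(bad), "edge-time-order")

  bad <- arg
  bad$sites$position <- 200 # outside the genome
  expect_error(validate_arg(bad), "site-position")

  bad <- arg
  bad$mutations$site[2] <- 5L
  expect_error(validate_arg(bad), "mutation-site-ref")

  bad <- arg
  bad$nodes$individual[1] <- 7L
  expect_error(validate_arg(bad), "node-individual-ref")

  bad <- arg
  bad$edges <- dplyr::bind_rows(bad$edges,
                                tibble::tibble(left = 20, right = 60,
                                               parent = 6L, child = 0L))
  expect_error(validate_arg(bad), "edge-child-overlap")
})

test_that("an ARG with zero sites is valid and empty-site queries behave", {
  arg <- make_random_arg(6, 0, seed = 1)
  expect_equal(nrow(arg$sites), 0)
  expect_s3_class(validate_arg(arg), "arg_tables")
  expect_error(resolve_states(arg, 0), "does not exist")
})

test_that("TSV round trip reproduces the tables bit-for-bit", {
  for (s in c(1, 2, 3)) {
    arg <- make_random_arg(25, 8, n_trees = 2, stacked_mutation_rate = 0.5,
                           seed = s) # ~50 nodes
    path <- withr::local_tempfile(fileext = ".tsv")
    write_arg(arg, path)
    back <- read_arg(path)
    expect_identical(back$nodes, arg$nodes)
    expect_identical(back$edges, arg$edges)
    expect_identical(back$sites, arg$sites)
    expect_identical(back$mutations, arg$mutations)
    expect_identical(back$individuals, arg$individuals)
    expect_identical(back$sequence_length, arg$sequence_length)
  }
})

test_that("malformed TSV input is rejected with the offending row", {
  arg <- make_example_arg()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_arg(arg, path)
  lines <- readLines(path)
  i <- grep("^#nodes", lines) + 2L
  lines[i] <- sub("^0\t", "zero\t", lines[i])
  writeLines(lines, path)
  expect_error(read_arg(path), "row 1")
  expect_error(read_arg("/nonexistent/file.tsv"), "not found")
})

test_that("tree_at returns the active parent array and is piecewise-constant", {
  # single tree: same parent array everywhere
  arg <- make_example_arg()
  t1 <- tree_at(arg, 0)
  t2 <- tree_at(arg, 99.9)
  expect_identical(t1$parent, t2$parent)
  expect_error(tree_at(arg, 100), "position")
  expect_error(tree_at(arg, -1), "position")

  # two trees, breakpoint at 50: distinct arrays each side, constant within
  arg2 <- two_tree_arg()
  left <- tree_at(arg2, 49)
  right <- tree_at(arg2, 50)
  expect_false(identical(left$parent, right$parent))
  expect_identical(tree_at(arg2, 0)$parent, left$parent)
  expect_identical(tree_at(arg2, 49.99)$parent, left$parent)
  expect_identical(tree_at(arg2, 99.9)$parent, right$parent)
  expect_equal(left$interval, c(0, 50))
  expect_equal(right$interval, c(50, 100))
  # parent array equals the edges active at the position
  pos <- 25
  act <- arg2$edges$left <= pos & pos < arg2$edges$right
  expect_identical(left$parent[arg2$edges$child[act] + 1L],
                   arg2$edges$parent[act])
})

test_that("state resolution honours back-mutations on the example tree", {
  arg <- make_example_arg()
  st <- resolve_states(arg, 0)
  # below the causal mutation on i (id 9): h=7, j=8, c=2, d=3, f=5 carry T
  expect_equal(st$state[st$node %in% c(2, 3, 5, 7, 8, 9)], rep("T", 6))
  # e (id 4) is reverted by the back-mutation; everything above i is ancestral
  expect_equal(st$state[st$node %in% c(0, 1, 4, 6, 10)], rep("A", 5))
})

test_that("a site with no mutations resolves to the ancestral state everywhere", {
  arg <- make_example_arg()
  arg$mutations <- arg$mutations[0, ]
  st <- resolve_states(arg, 0)
  expect_equal(unique(st$state), "A")
  expect_equal(allele_frequency(arg, 0, "A"), 1)
  expect_equal(allele_frequency(arg, 0, "T"), 0)
})

test_that("state resolution matches the root-path-walk oracle on random ARGs", {
  for (s in 1:25) {
    arg <- make_random_arg(n_samples = sample(4:40, 1), n_sites = 5,
                           n_trees = sample(1:3, 1),
                           stacked_mutation_rate = 0.6, seed = s)
    expect_lte(nrow(arg$nodes), 200)
    for (site in arg$sites$id) {
      expect_identical(resolve_states(arg, site)$state, oracle_states(arg, site))
    }
  }
})

test_that("stacked mutations on one node need parent links or times", {
  arg <- make_example_arg()
  # two unordered mutations on the same node at the same site
  arg$mutations <- tibble::tibble(
    id = 0:1, site = 0L, node = c(9L, 9L), derived_state = c("T", "G"),
    parent = NA_integer_, time = NA_real_
  )
  expect_error(resolve_states(arg, 0), "mutation-order")
  # ...but a parent link disambiguates: the chain tail wins
  arg$mutations$parent <- c(NA_integer_, 0L)
  st <- resolve_states(arg, 0)
  expect_equal(st$state[st$node == 9], "G")
})

test_that("allele frequencies are sample-based and sum to one over alleles", {
  arg <- make_example_arg()
  expect_equal(allele_frequency(arg, 0, "T"), 0.5)
  expect_equal(allele_frequency(arg, 0, "A"), 0.5)
  expect_equal(allele_frequency(arg, 0, "G"), 0)

  for (s in 1:10) {
    arg <- make_random_arg(12, 6, stacked_mutation_rate = 0.7, seed = 100 + s)
    for (site in arg$sites$id) {
      alleles <- unique(c(arg$sites$ancestral_state[site + 1L],
                          arg$mutations$derived_state))
      total <- sum(vapply(alleles,
                          function(a) allele_frequency(arg, site, a), 0))
      expect_equal(total, 1)
    }
  }
})

test_that("individual_nodes maps diploid individuals to their two genomes", {
  arg <- make_example_arg()
  m <- individual_nodes(arg)
  expect_equal(m$individual_id, 0:2)
  expect_equal(m$nodes, list(c(0L, 1L), c(2L, 3L), c(4L, 5L)))
})
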