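test_that("hamming_matrix matches the nested-loop oracle", {
  expect_equal(hamming_matrix(c("AAA", "AAA"))[1, 2], 0L)
  expect_equal(hamming_matrix(c("AAA", "ATA"))[1, 2], 1L)
  set.seed(12)
  seqs <- replicate(10, paste0(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = ""))
  expect_equal(unname(hamming_matrix(seqs)), oracle_hamming(seqs))
  expect_error(hamming_matrix(c("AA", "AAA")), class = "mothwaves_alignment_error")
})

test_that("parsimony probability decreases in steps and the limit is monotone in length", {
  p <- vapply(1:10, parsimony_probability, numeric(1), length_bp = 590)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
  expect_gte(parsimony_limit(1180, 0.95)$max_steps,
             parsimony_limit(590, 0.95)$max_steps)
  # relaxing alpha can only extend the connection limit, never shrink it
  expect_gte(parsimony_limit(50, 0.05)$max_steps,
             parsimony_limit(50, 0.95)$max_steps)
  expect_lte(parsimony_limit(50, 1e-6)$max_steps, 50L)
  expect_error(parsimony_limit(590, 1.2), class = "mothwaves_input_error")
  expect_error(parsimony_limit(590, 0), class = "mothwaves_input_error")
})

test_that("the 95% connection limit for the 590-bp fragment is stable", {
  # regression constant recorded from the package's own estimator at build time
  expect_equal(parsimony_limit(590, 0.95)$max_steps, 7L)
})

make_ht <- function(seqs, counts, pop = "p1") {
  aln <- tiny_aln(rep(seqs, counts))
  collapse_haplotypes(aln, uniform_popmap(aln, pop))
}

test_that("simple topologies come out as specified", {
  # single haplotype: one node, no edges
  ht1 <- make_ht("ACGT", 3)
  net1 <- build_network(ht1)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)

  # chained 1-step distances: path with no inferred nodes
  ht2 <- make_ht(c("AAA", "AAT", "ATT"), c(10, 5, 1))
  net2 <- build_network(ht2)
  expect_equal(sum(net2$nodes$kind == "inferred"), 0)
  expect_equal(nrow(net2$edges), 2)
  expect_setequal(
    paste(pmin(net2$edges$from, net2$edges$to), pmax(net2$edges$from, net2$edges$to)),
    c("H1 H2", "H2 H3")
  )
})

test_that("a planted star genealogy yields a star with inferred nodes at 2 steps", {
  sim <- simulate_haplotypes(
    n_samples = 26, seq_length = 100,
    founder_spectrum = data.frame(count = 20, steps = 0),
    n_singletons = 6, singleton_steps = c(1, 1, 1, 2, 2, 2),
    n_demes = 1, seed = 14
  )
  ht <- collapse_haplotypes(sim$alignment, sim$popmap)
  net <- build_network(ht)
  g <- glance(net)
  expect_equal(g$n_components, 1)
  # exactly one inferred node per 2-step singleton
  steps <- sim$manifest$planted_spectrum$steps
  expect_equal(g$n_inferred, sum(steps == 2))
  # star: contracting inferred nodes, the center touches every ray
  centre <- net$nodes$name[which.max(net$nodes$frequency)]
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[centre]), length(steps) - 1)
})

test_that("edges never span more than one mutational step", {
  sim <- simulate_haplotypes(seed = 23)
  ht <- collapse_haplotypes(sim$alignment, sim$popmap)
  net <- build_network(ht)
  seqs <- setNames(ht$haplotypes$sequence, ht$haplotypes$name)
  sampled_edges <- net$edges[net$edges$from %in% names(seqs) &
                               net$edges$to %in% names(seqs), ]
  if (nrow(sampled_edges) > 0) {
    d <- mapply(function(a, b) sum(strsplit(seqs[[a]], "")[[1]] !=
                                     strsplit(seqs[[b]], "")[[1]]),
                sampled_edges$from, sampled_edges$to)
    expect_true(all(d == 1))
  }
  # inferred nodes are abstract intermediates with degree >= 2
  deg <- table(c(net$edges$from, net$edges$to))
  inferred <- net$nodes$name[net$nodes$kind == "inferred"]
  expect_true(all(deg[inferred] >= 2))
})

test_that("connected haplotypes respect the observed-distance path bound", {
  sim <- simulate_haplotypes(seed = 37)
  ht <- collapse_haplotypes(sim$alignment, sim$popmap)
  net <- build_network(ht)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = as.data.frame(net$nodes))
  d_obs <- hamming_matrix(setNames(ht$haplotypes$sequence, ht$haplotypes$name))
  nm <- ht$haplotypes$name
  d_net <- igraph::distances(g, v = nm, to = nm)
  same_comp <- is.finite(d_net)
  expect_true(all(d_net[same_comp] <= d_obs[same_comp]))
})

test_that("pairs beyond the limit stay in separate components", {
  seqs <- c(strrep("A", 20), paste0(strrep("T", 10), strrep("A", 10)))
  ht <- make_ht(seqs, c(5, 3))
  net <- build_network(ht, limit = parsimony_limit(20, 0.95))
  expect_lt(net$limit$max_steps, 10)
  expect_equal(glance(net)$n_components, 2)
})

test_that("network construction is deterministic", {
  sim <- simulate_haplotypes(seed = 41)
  ht <- collapse_haplotypes(sim$alignment, sim$popmap)
  n1 <- build_network(ht)
  n2 <- build_network(ht)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("export round-trips through GML and TSV", {
  ht <- make_ht(c("AAA", "AAT", "ATT"), c(10, 5, 1))
  net <- build_network(ht)
  gml <- withr::local_tempfile(fileext = ".gml")
  export_network(net, gml, "gml")
  back <- import_network(gml, "gml")
  expect_setequal(back$nodes$name, net$nodes$name)
  expect_equal(back$nodes$frequency[match(net$nodes$name, back$nodes$name)],
               net$nodes$frequency)
  expect_equal(back$nodes$kind[match(net$nodes$name, back$nodes$name)],
               net$nodes$kind)
  expect_equal(nrow(back$edges), nrow(net$edges))

  stem <- withr::local_tempfile()
  export_network(net, stem, "tsv")
  back2 <- import_network(stem, "tsv")
  expect_equal(back2$nodes, net$nodes)
  expect_equal(back2$edges, net$edges)

  # byte-stable exports across runs
  gml2 <- withr::local_tempfile(fileext = ".gml")
  export_network(build_network(ht), gml2, "gml")
  expect_identical(readLines(gml), readLines(gml2))
  expect_s3_class(autoplot(net), "ggplot")
})
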