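test_that("modified cosine is 1 on self and 0 with nothing pairable", {
  s <- toy_spectrum("s", 400, c(100, 150, 200, 250), c(5, 20, 80, 40))
  self <- modified_cosine(s, s)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$matches, 4L)
  far <- toy_spectrum("t", 400.5, c(111, 163, 217, 269))
  expect_equal(modified_cosine(s, far), list(score = 0, matches = 0L))
})

test_that("modified cosine equals the brute-force pairing oracle on toys", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    p1 <- 380 + runif(1, 0, 40)
    p2 <- p1 - sample(c(0, 14.0157, 18.0106), 1)
    base <- sort(runif(6, 100, 350))
    a <- toy_spectrum("a", p1, sort(sample(base, n1)) + rnorm(n1, 0, 2e-3),
                      runif(n1, 10, 100))
    b <- toy_spectrum("b", p2,
                      sort(sample(base, n2)) - (p1 - p2) * rbinom(n2, 1, .5) +
                        rnorm(n2, 0, 2e-3),
                      runif(n2, 10, 100))
    got <- modified_cosine(a, b)
    want <- oracle_modified_cosine(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    # greedy pairing never beats the exhaustive optimum
    greedy <- modified_cosine(a, b, exact_limit = 0L)
    expect_lte(greedy$score, want$score + 1e-9)
    # symmetry and bounds
    expect_equal(modified_cosine(b, a)$score, got$score, tolerance = 1e-9)
    expect_gte(got$score, 0)
    expect_lte(got$score, 1)
  }
})

test_that("modified cosine reduces to plain cosine at zero precursor shift", {
  a <- toy_spectrum("a", 500, c(100, 200, 300), c(1, 4, 9))
  b <- toy_spectrum("b", 500, c(100, 200, 300), c(9, 4, 1))
  wa <- sqrt(c(1, 4, 9)); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(c(9, 4, 1)); wb <- wb / sqrt(sum(wb^2))
  expect_equal(modified_cosine(a, b)$score, sum(wa * wb), tolerance = 1e-12)
})

test_that("a clique of near-identical spectra forms one fully linked component", {
  fam <- toy_family("cl", seq(120, 330, by = 30), n = 5, precursor = 450)
  net <- build_network(fam, network_params(min_matched_peaks = 6L))
  expect_equal(max(net$nodes$component), 1L)
  expect_false(any(net$nodes$orphan))
  expect_equal(nrow(net$edges), choose(5, 2))
})

test_that("two separated families give exactly two components", {
  famA <- toy_family("A", seq(120, 330, by = 30), n = 4, precursor = 450,
                     seed = 1)
  famB <- toy_family("B", seq(135, 345, by = 30) + 4.3, n = 4,
                     precursor = 800, seed = 2)
  net <- build_network(c(famA, famB))
  expect_equal(sort(unique(na.omit(net$nodes$component))), c(1L, 2L))
  compA <- net$nodes$component[startsWith(net$nodes$spectrum_id, "A")]
  compB <- net$nodes$component[startsWith(net$nodes$spectrum_id, "B")]
  expect_length(unique(compA), 1L)
  expect_length(unique(compB), 1L)
  expect_false(unique(compA) == unique(compB))
})

test_that("all-dissimilar spectra are orphaned with zero components", {
  specs <- lapply(1:4, function(k) {
    toy_spectrum(paste0("o", k), 300 + 50 * k,
                 sort(runif(6, 60, 280)) + k * 7)
  })
  net <- build_network(specs)
  expect_true(all(net$nodes$orphan))
  expect_equal(nrow(net$edges), 0L)
  expect_true(all(is.na(net$nodes$component)))
})

test_that("network construction is invariant to spectrum input order", {
  fam <- c(toy_family("A", seq(120, 330, by = 30), n = 3, precursor = 450),
           toy_family("B", seq(140, 350, by = 30) + 2.7, n = 3,
                      precursor = 700, seed = 9))
  net1 <- build_network(fam)
  net2 <- build_network(rev(fam))
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$edges, net2$edges)
})

test_that("node annotation and majority-vote component classes work on
           library-derived spectra", {
  lib <- load_library()
  recs <- lib[lib$id %in% c(80, 95, 107), ]  # chebulanin / chebulagic / chebulinic
  gen <- generate_spectra(recs, fragment_noise_sd = 0, seed = 5)
  net <- build_network(gen$spectra,
                       network_params(min_cosine = 0.2,
                                      min_matched_peaks = 2L))
  net <- annotate_nodes(net)
  expect_equal(sort(net$nodes$annotation_id), c(80L, 95L, 107L))
  expect_true(all(net$nodes$annotation_class == "chebulic ellagitannin"))
  net <- enhance_component_classes(net)
  cc <- net$component_classes
  expect_true(all(cc$class == "chebulic ellagitannin"))
})

test_that("component labelling is majority-vote with propagation to
           unannotated members", {
  fam <- toy_family("m", seq(120, 330, by = 30), n = 3, precursor = 450)
  net <- build_network(fam, network_params(min_matched_peaks = 6L))
  net$nodes$annotation_class <- c("gallotannin", "gallotannin", NA)
  net$nodes$annotation_id <- c(1L, 2L, NA)
  net$nodes$annotation_name <- c("x", "y", NA)
  net <- enhance_component_classes(net)
  expect_equal(net$component_classes$class, "gallotannin")
  expect_equal(net$nodes$propagated_class[3], "gallotannin")
  # with no annotations at all the component is unclassified
  net$nodes$annotation_class <- NA_character_
  net <- enhance_component_classes(net)
  expect_equal(net$component_classes$class, "unclassified")
})

test_that("GraphML export writes a readable graph with attributes", {
  fam <- toy_family("g", seq(120, 330, by = 30), n = 3, precursor = 450)
  net <- build_network(fam)
  path <- tempfile(fileext = ".graphml")
  write_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("cosine" %in% igraph::edge_attr_names(g))
  expect_true("precursor_mz" %in% igraph::vertex_attr_names(g))
})
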