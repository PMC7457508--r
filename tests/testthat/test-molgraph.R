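test_that("build_graph constructs vertices and edges from adjacency", {
  g <- build_graph(c(6L, 6L), rbind(c(0, 1), c(1, 0)))
  expect_equal(g$num_vertices, 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges[1, ], c(1L, 2L))

  g1 <- build_graph(8L, matrix(0, 1, 1))
  expect_equal(g1$num_vertices, 1L)
  expect_equal(nrow(g1$edges), 0L)

  benz <- make_molecule("benzene")
  gb <- build_graph(benz$atomic_numbers, benz$adjacency)
  expect_equal(gb$num_vertices, 12L)
  expect_equal(nrow(gb$edges), 12L)
})

test_that("build_graph rejects malformed adjacency input", {
  expect_error(
    build_graph(c(6L, 6L), rbind(c(0, 1, 0), c(1, 0, 1))),
    class = "symrmsd_contract_error"
  )
  expect_error(
    build_graph(c(6L, 6L), rbind(c(0, 1), c(0, 0))),
    class = "symrmsd_contract_error"
  )
  expect_error(
    build_graph(c(6L, 6L, 6L), rbind(c(0, 1), c(1, 0))),
    class = "symrmsd_contract_error"
  )
  expect_error(
    build_graph(c(6L, 6L), rbind(c(1, 1), c(1, 0))),
    class = "symrmsd_contract_error"
  )
})

test_that("labels break symmetry: O-C-N path has exactly the identity", {
  adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  g <- build_graph(c(8L, 6L, 7L), adj)
  maps <- enumerate_isomorphisms(g, g)
  expect_length(maps, 1L)
  expect_equal(maps[[1]], 1:3)
})

test_that("benzene graph has exactly the 12 automorphisms found by brute force", {
  benz <- make_molecule("benzene")
  g <- build_graph(benz$atomic_numbers, benz$adjacency)
  maps <- enumerate_isomorphisms(g, g)
  expect_length(maps, 12L)
  bf <- brute_force_isomorphisms(
    benz$atomic_numbers, benz$adjacency,
    benz$atomic_numbers, benz$adjacency
  )
  key <- function(m) paste(m, collapse = ",")
  expect_setequal(vapply(maps, key, ""), vapply(bf, key, ""))
})

test_that("non-isomorphic graphs raise a diagnostic error, not an empty list", {
  ring <- build_graph(
    rep(6L, 6),
    adjacency_from_edges_test(6, rbind(cbind(1:5, 2:6), c(6, 1)))
  )
  path <- build_graph(
    rep(6L, 6),
    adjacency_from_edges_test(6, cbind(1:5, 2:6))
  )
  expect_error(
    enumerate_isomorphisms(ring, path),
    "bond counts",
    class = "symrmsd_not_isomorphic"
  )
  small <- build_graph(c(6L, 6L), rbind(c(0, 1), c(1, 0)))
  expect_error(
    enumerate_isomorphisms(ring, small),
    "vertex counts",
    class = "symrmsd_not_isomorphic"
  )
  hetero <- build_graph(
    c(6L, 6L, 6L, 6L, 6L, 8L),
    adjacency_from_edges_test(6, cbind(1:5, 2:6))
  )
  expect_error(
    enumerate_isomorphisms(path, hetero),
    "element",
    class = "symrmsd_not_isomorphic"
  )
})

test_that("every returned mapping transports the reference edge set onto the probe's", {
  for (seed in 1:10) {
    pair <- small_fixture_pair(seed)
    g_ref <- build_graph(pair$ref$atomic_numbers, pair$ref$adjacency)
    g_probe <- build_graph(pair$probe$atomic_numbers, pair$probe$adjacency)
    for (m in enumerate_isomorphisms(g_ref, g_probe)) {
      expect_true(all(sort(m) == seq_along(m)))
      expect_identical(pair$ref$atomic_numbers, pair$probe$atomic_numbers[m])
      expect_identical(
        pair$ref$adjacency != 0,
        pair$probe$adjacency[m, m, drop = FALSE] != 0
      )
    }
  }
})

test_that("VF2 enumeration matches exhaustive search on small molecules", {
  for (seed in 1:25) {
    pair <- small_fixture_pair(seed)
    g_ref <- build_graph(pair$ref$atomic_numbers, pair$ref$adjacency)
    g_probe <- build_graph(pair$probe$atomic_numbers, pair$probe$adjacency)
    maps <- enumerate_isomorphisms(g_ref, g_probe)
    bf <- brute_force_isomorphisms(
      pair$ref$atomic_numbers, pair$ref$adjacency,
      pair$probe$atomic_numbers, pair$probe$adjacency
    )
    key <- function(m) paste(m, collapse = ",")
    expect_setequal(vapply(maps, key, ""), vapply(bf, key, ""))
  }
})

test_that("self-isomorphisms always include the identity", {
  for (seed in 1:10) {
    m <- small_fixture_pair(seed)$ref
    g <- build_graph(m$atomic_numbers, m$adjacency)
    maps <- enumerate_isomorphisms(g, g)
    key <- function(x) paste(x, collapse = ",")
    expect_true(key(seq_len(g$num_vertices)) %in% vapply(maps, key, ""))
  }
})

test_that("disconnected two-fragment graphs are matched over the whole vertex set", {
  dp <- make_molecule("disconnected-pair")
  g <- build_graph(dp$atomic_numbers, dp$adjacency)
  maps <- enumerate_isomorphisms(g, g)
  # identity plus the swap of the two identical C-O fragments
  expect_length(maps, 2L)
  key <- function(m) paste(m, collapse = ",")
  expect_setequal(vapply(maps, key, ""), c("1,2,3,4", "3,4,1,2"))
})

test_that("graph digests are deterministic and edge-sensitive", {
  benz <- make_molecule("benzene")
  g1 <- build_graph(benz$atomic_numbers, benz$adjacency)
  g2 <- build_graph(benz$atomic_numbers, benz$adjacency)
  expect_identical(graph_digest(g1), graph_digest(g2))

  adj <- benz$adjacency
  adj[1, 2] <- 0
  adj[2, 1] <- 0
  g3 <- build_graph(benz$atomic_numbers, adj)
  expect_false(identical(graph_digest(g1), graph_digest(g3)))

  lab <- benz$atomic_numbers
  lab[1] <- 7L
  g4 <- build_graph(lab, benz$adjacency)
  expect_false(identical(graph_digest(g1), graph_digest(g4)))
})

test_that("cache returns the inserted mapping list unchanged", {
  benz <- make_molecule("benzene")
  g <- build_graph(benz$atomic_numbers, benz$adjacency)
  cache <- new_iso_cache()
  first <- symrmsd:::cached_isomorphisms(cache, g, g)
  again <- symrmsd:::cached_isomorphisms(cache, g, g)
  expect_identical(first, again)
  expect_identical(first, enumerate_isomorphisms(g, g))
})
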