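test_that("standard RMSD evaluates its closed form", {
  a <- random_coords(5, 1)
  expect_identical(rmsd_standard(a, a), 0)

  shifted <- sweep(a, 2, -c(3, 4, 0))
  expect_equal(rmsd_standard(a, shifted), 5)

  expect_equal(
    rmsd_standard(rbind(c(0, 0, 0), c(1, 0, 0)), matrix(0, 2, 3)),
    sqrt(1 / 2)
  )
  expect_error(rmsd_standard(a, a[1:3, ]), class = "symrmsd_contract_error")
})

test_that("benzene after a mirror operation: positional RMSD inflated, corrected RMSD zero", {
  ref <- make_molecule("benzene")
  mirrored <- make_molecule("benzene", mirror = c(1, 0, 0))
  expect_gt(rmsd_standard(ref$coords, mirrored$coords), 1)
  expect_lt(rmsd_symmetry(ref, mirrored), 1e-9)
  expect_lt(rmsd_symmetry(ref, mirrored, minimize = TRUE), 1e-9)
})

test_that("molecules without topological symmetry reduce to the standard RMSD", {
  # all-distinct elements force the identity mapping
  ref <- make_molecule("linear-chain", k = 4, elements = c(6L, 7L, 8L, 16L))
  probe <- make_molecule("linear-chain",
    k = 4, elements = c(6L, 7L, 8L, 16L),
    jitter_sigma = 0.4, seed = 9
  )
  expect_identical(
    rmsd_symmetry(ref, probe),
    rmsd_standard(ref$coords, probe$coords)
  )
})

test_that("symmetry-corrected RMSD equals the brute-force permutation minimum", {
  for (seed in 1:25) {
    pair <- small_fixture_pair(seed)
    expect_equal(
      rmsd_symmetry(pair$ref, pair$probe),
      brute_force_symm_rmsd(pair$ref, pair$probe),
      tolerance = 1e-9
    )
    expect_equal(
      rmsd_symmetry(pair$ref, pair$probe, minimize = TRUE),
      brute_force_symm_rmsd(pair$ref, pair$probe, minimize = TRUE),
      tolerance = 1e-9
    )
  }
})

test_that("probe relabelling by a graph automorphism changes nothing", {
  ref <- make_molecule("benzene", jitter_sigma = 0.05, seed = 4)
  probe <- make_molecule("benzene", jitter_sigma = 0.2, seed = 5)
  base <- rmsd_symmetry(ref, probe)
  g <- build_graph(probe$atomic_numbers, probe$adjacency)
  for (m in enumerate_isomorphisms(g, g)) {
    relabelled <- molecule(
      probe$coords[m, , drop = FALSE],
      probe$atomic_numbers[m],
      probe$adjacency[m, m, drop = FALSE]
    )
    expect_equal(rmsd_symmetry(ref, relabelled), base, tolerance = 1e-12)
  }
})

test_that("the ordering chain among RMSD flavours holds on every fixture", {
  for (seed in 1:15) {
    pair <- small_fixture_pair(seed)
    r_std <- rmsd_standard(pair$ref$coords, pair$probe$coords)
    r_qcp <- rmsd_qcp(pair$ref$coords, pair$probe$coords)
    r_sym <- rmsd_symmetry(pair$ref, pair$probe)
    r_sym_min <- rmsd_symmetry(pair$ref, pair$probe, minimize = TRUE)
    expect_lte(r_qcp, r_std + 1e-12)
    expect_lte(r_sym_min, r_sym + 1e-12)
    # the corrected value can only improve on the positional one when the
    # identity pairing is itself a valid isomorphism (same stored order)
    if (identical(pair$ref$adjacency, pair$probe$adjacency) &&
      identical(pair$ref$atomic_numbers, pair$probe$atomic_numbers)) {
      expect_lte(r_sym, r_std + 1e-12)
    }
    expect_lte(
      rmsd_hungarian(pair$ref, pair$probe), r_std + 1e-12
    )
  }
})

test_that("all four flavours are symmetric in their two arguments", {
  pair <- small_fixture_pair(42)
  a <- pair$ref
  b <- pair$probe
  expect_equal(rmsd_standard(a$coords, b$coords), rmsd_standard(b$coords, a$coords))
  expect_equal(rmsd_qcp(a$coords, b$coords), rmsd_qcp(b$coords, a$coords),
    tolerance = 1e-9
  )
  expect_equal(rmsd_hungarian(a, b), rmsd_hungarian(b, a), tolerance = 1e-9)
  expect_equal(rmsd_symmetry(a, b), rmsd_symmetry(b, a), tolerance = 1e-9)
})

test_that("many probes return one value each, identical with cache on and off", {
  ref <- make_molecule("benzene")
  probes <- lapply(1:10, function(s) {
    p <- make_molecule("benzene", jitter_sigma = 0.3, seed = s)
    p$coords <- apply_transform(p$coords, random_rigid_transform(s + 50))
    p
  })
  on_ <- rmsd_symmetry(ref, probes, cache = TRUE)
  off <- rmsd_symmetry(ref, probes, cache = FALSE)
  expect_length(on_, 10L)
  expect_identical(on_, off)

  on_min <- rmsd_symmetry(ref, probes, minimize = TRUE, cache = TRUE)
  off_min <- rmsd_symmetry(ref, probes, minimize = TRUE, cache = FALSE)
  expect_identical(on_min, off_min)

  # a shared external cache gives the same numbers again
  cache <- new_iso_cache()
  expect_identical(rmsd_symmetry(ref, probes, cache = cache), on_)
  expect_identical(rmsd_symmetry(ref, probes, cache = cache), on_)
})

test_that("missing adjacency and non-isomorphic probes are rejected", {
  ref <- make_molecule("benzene")
  bare <- molecule(ref$coords, ref$atomic_numbers)
  expect_error(rmsd_symmetry(bare, ref), class = "symrmsd_contract_error")
  expect_error(rmsd_symmetry(ref, bare), class = "symrmsd_contract_error")
  eth <- make_molecule("ethanol")
  expect_error(rmsd_symmetry(ref, eth), class = "symrmsd_not_isomorphic")
})

test_that("array-level front ends agree with the molecule-level functions", {
  pair <- small_fixture_pair(7)
  a <- pair$ref
  b <- pair$probe
  expect_identical(
    rmsd(a$coords, b$coords, a$atomic_numbers, b$atomic_numbers),
    rmsd_standard(a$coords, b$coords)
  )
  expect_identical(
    rmsd(a$coords, b$coords, minimize = TRUE),
    rmsd_qcp(a$coords, b$coords)
  )
  expect_identical(
    hrmsd(a$coords, b$coords, a$atomic_numbers, b$atomic_numbers),
    rmsd_hungarian(a, b)
  )
  expect_identical(
    symmrmsd(
      a$coords, list(b$coords, b$coords),
      a$atomic_numbers, b$atomic_numbers,
      a$adjacency, b$adjacency
    ),
    rmsd_symmetry(a, list(b, b))
  )
  expect_error(
    rmsd(a$coords, b$coords, c(6L, 6L), c(6L, 8L)),
    class = "symrmsd_contract_error"
  )
})
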