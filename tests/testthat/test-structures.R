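test_that("subcomplex relation is containment, including reflexivity", {
  expect_true(isSubcomplex("x", c("x", "y")))
  expect_false(isSubcomplex(c("x", "y"), c("y", "z")))
  expect_true(isSubcomplex(c("x", "y"), c("x", "y")))
})

test_that("splitComplex yields all facets in canonical order", {
  expect_equal(splitComplex(c("x", "y", "z")),
               list(c("x", "y"), c("x", "z"), c("y", "z")))
  expect_equal(splitComplex(c("x", "y")), list("x", "y"))
  expect_error(splitComplex("x"), "cannot split")
  # combinatorial identity on random complexes
  vars <- letters[1:6]
  for (k in 2:5) {
    cx <- sort(sample(vars, k))
    facets <- splitComplex(cx)
    expect_length(facets, k)
    expect_true(all(vapply(facets, isSubcomplex, logical(1), b = cx)))
  }
})

test_that("canonicalizeComplexes removes duplicates and subsumed members", {
  expect_equal(canonicalizeComplexes(list("x", c("x", "y"))),
               list(c("x", "y")))
  expect_equal(canonicalizeComplexes(list(c("y", "z"), c("x", "y"))),
               list(c("x", "y"), c("y", "z")))
  expect_equal(canonicalizeComplexes(list()), list())
  # idempotence and subsumption-freedom on random candidate sets
  set.seed(42)
  for (rep in 1:20) {
    cxs <- replicate(sample(2:6, 1),
                     sort(sample(letters[1:5], sample(1:4, 1))),
                     simplify = FALSE)
    once <- canonicalizeComplexes(cxs)
    expect_identical(canonicalizeComplexes(once), once)
    if (length(once) >= 2) {
      for (i in seq_along(once)) for (j in seq_along(once)) {
        if (i != j) expect_false(isSubcomplex(once[[i]], once[[j]]))
      }
    }
  }
})

test_that("split followed by canonicalize is subsumption-free", {
  cx <- c("a", "b", "c", "d")
  out <- canonicalizeComplexes(splitComplex(cx))
  expect_length(out, 4)
  expect_true(all(lengths(out) == 3))
})

test_that("structure construction enforces the subsumption and membership rules", {
  ok <- higherOrderStructure(c("x", "y", "z"),
                             list(z = list("z", c("x", "y"))))
  expect_s4_class(ok, "HigherOrderStructure")
  expect_equal(neighborsOf(ok, "z"), list(c("x", "y"), "z"))
  expect_error(higherOrderStructure(c("x", "z"),
                                    list(z = list("z", c("x", "z")))),
               "subsumed")
  expect_error(higherOrderStructure(c("x", "y"),
                                    list(x = list("w"))),
               "unknown")
})

test_that("hyperedge lists round-trip through the plain-text format", {
  st <- higherOrderStructure(c("x", "y", "z"),
                             list(x = list("x", "y"),
                                  y = list("y", c("x", "z")),
                                  z = list("z", c("x", "y"))))
  f <- tempfile(fileext = ".hyperedges")
  writeHyperedges(st, f)
  back <- readHyperedges(f, nodes = c("x", "y", "z"))
  expect_true(structuresEqual(st, back))
})

test_that("pairwise projection collapses complexes to neighbour sets", {
  st <- higherOrderStructure(c("x", "y", "z"),
                             list(z = list("z", c("x", "y"))))
  expect_equal(pairwiseNeighbors(st)$z, c("x", "y", "z"))
})
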