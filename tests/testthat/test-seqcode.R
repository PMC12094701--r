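test_that("the periodic labeling honours rows, offsets and period vectors", {
  a <- arr7()
  expect_equal(elementAt(a, c(0, 0)), 1L)
  expect_equal(elementAt(a, c(3, 0)), 4L)
  # horizontal period k and the full period basis
  pts <- as.matrix(expand.grid(q = -3:3, r = -3:3))
  pb <- periodBasisAxial(a)
  expect_equal(elementAt(a, pts),
               elementAt(a, sweep(pts, 2, c(rowRepeat(a), 0), "+")))
  expect_equal(elementAt(a, pts),
               elementAt(a, sweep(pts, 2, pb[, 2], "+")))
  # disjoint rows cycle with vertical period R
  a9 <- arr9()
  expect_equal(elementAt(a9, c(0, 0)), 1L)
  expect_equal(elementAt(a9, c(0, 1)), 4L)
  expect_equal(elementAt(a9, c(0, 2)), 7L)
  expect_equal(elementAt(a9, c(0, 3)), 1L)
})

test_that("structurally inadmissible arrangements are rejected at construction", {
  expect_error(Arrangement(list(1:7), 1), "translation")    # offset 1
  expect_error(Arrangement(list(1:7), 0), "translation")
  expect_error(Arrangement(list(1:4), 2), "translation")    # k = 4, R = 1
  expect_error(Arrangement(list(1:2), 0), "at least 3")
  expect_error(Arrangement(list(1:3, 2:4), c(0, 0)), "disjoint")
})

test_that("axiom validation matches the known translation cases", {
  expect_true(isValid(validateArrangement(arr7(2))))
  expect_true(isValid(validateArrangement(arr7(4))))
  rep3 <- validateArrangement(arr7(3))     # translation by three fails
  expect_false(isValid(rep3))
  v <- violations(rep3)
  expect_true(any(v$axiom == 1L))          # ambiguous ordered pair
  expect_true(any(v$axiom == 3L))          # surround not six distinct ids
})

test_that("independent brute-force oracle agrees with validation (n <= 10)", {
  for (n in 7:10) {
    for (a in allCandidates(n)) {
      expect_identical(isValid(validateArrangement(a)), oracleValid(a),
                       info = sprintf("n=%d k=%d off=%s", n, rowRepeat(a),
                                      paste(arrangementOffsets(a),
                                            collapse = ",")))
    }
  }
})

test_that("canonical keys are orbit invariants separating the mirror pair", {
  k2 <- canonicalForm(arr7(2)); k4 <- canonicalForm(arr7(4))
  expect_false(k2 == k4)
  expect_identical(canonicalForm(arr7(2), TRUE), canonicalForm(arr7(4), TRUE))
  # relabeling invariance: permute ids in the stored row
  perm <- c(3L, 6L, 1L, 7L, 4L, 2L, 5L)
  relab <- Arrangement(list(perm[1:7]), 2L)
  expect_identical(canonicalForm(relab), k2)
  # a rotated representation of the same code (rows along a diagonal)
  expect_identical(canonicalForm(arr9(c(0, 0, 0)), TRUE),
                   canonicalForm(arr9(c(1, 2, 0)), TRUE))
})

test_that("enumeration finds nothing below 7 and the known small solutions", {
  for (n in 3:6) expect_length(enumerateArrangements(n), 0L)
  expect_length(enumerateArrangements(7, moduloReflection = FALSE), 2L)
  expect_length(enumerateArrangements(7, moduloReflection = TRUE), 1L)
  e8 <- enumerateArrangements(8)
  expect_gte(length(e8), 1L)
  expect_true(any(vapply(e8, function(a)
    identical(repeatLengths(a), c(4L, 8L, 8L)), logical(1))))
})

test_that("single-element sublattices have index n and the predicted geometry", {
  a7 <- arr7()
  b7 <- sublatticeBasis(a7)
  expect_equal(abs(det(b7)), 7 * sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(min(sqrt(rowSums(gridseq:::latticeAxes(b7)^2))), sqrt(7),
               tolerance = 1e-9)
  expect_identical(classifyLattice(b7), "hexagonal")
  # the basis really generates the occurrence set of each element
  for (e in c(1L, 4L)) {
    cc <- fieldCenters(a7, e, extent = 12, spacing = 1)
    expect_gt(nrow(cc), 10)
    ids <- assignElements(a7, cc, spacing = 1)
    expect_true(all(ids == e))
  }
  # hexagonal 9-element solution: shortest vector 3
  b9 <- sublatticeBasis(arr9())
  expect_identical(classifyLattice(b9), "hexagonal")
  expect_equal(min(sqrt(rowSums(gridseq:::latticeAxes(b9)^2))), 3,
               tolerance = 1e-9)
  expect_equal(abs(det(b9)), 9 * sqrt(3) / 2, tolerance = 1e-9)
})

test_that("axis repeat lengths divide n, are at least 3 and match known cases", {
  expect_identical(repeatLengths(arr7()), c(7L, 7L, 7L))
  expect_identical(repeatLengths(arr9()), c(3L, 3L, 3L))
  e8 <- enumerateArrangements(8)
  expect_identical(repeatLengths(e8[[1]]), c(4L, 8L, 8L))
  for (n in 7:10) for (a in gridseq:::.validCandidates(n)) {
    rl <- repeatLengths(a)
    expect_true(all(rl >= 3L))
    expect_true(all(n %% rl == 0L))
  }
})

test_that("the grid-map table reproduces the published geometry rows", {
  tab <- gridMapTable(7, 9)
  r7 <- tab[tab$n == 7, ]
  expect_equal(nrow(r7), 1L)
  expect_identical(r7$repeats, "7, 7, 7")
  expect_identical(r7$lattice_type, "hexagonal")
  expect_equal(r7$angle_deg, 10.9)
  r9 <- tab[tab$n == 9, ]
  expect_true(any(r9$repeats == "3, 3, 3" & r9$lattice_type == "hexagonal" &
                    r9$angle_deg == 0))
  expect_setequal(r9$repeats[r9$lattice_type == "oblique"],
                  c("3, 9, 9"))
})

test_that("field centres fill a window at the sublattice density", {
  a <- arr7()
  cc <- fieldCenters(a, 1L, extent = 0.5, spacing = 1)
  expect_lte(nrow(cc), 1L)
  cc <- fieldCenters(a, 3L, extent = 40, spacing = 1)
  dens <- nrow(cc) / 40^2
  expect_equal(dens, 1 / (7 * sqrt(3) / 2), tolerance = 0.15)
  ring <- ringFieldCenters(a, 1L, spacing = 2, center = c(10, 10))
  expect_equal(nrow(ring), 7L)
  d <- sqrt(rowSums(sweep(ring[-1, ], 2, ring[1, ], "-")^2))
  expect_equal(d, rep(2 * sqrt(7), 6), tolerance = 1e-9)
})
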