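test_that("parseStructure splits chains, drops HETATM and duplicate altlocs", {
  clouds <- parseStructure(twoChainPdb())
  expect_length(clouds, 2L)
  expect_equal(vapply(clouds, chainID, ""), c("A", "B"))
  expect_equal(vapply(clouds, nAtoms, 1L), c(3L, 2L))
  ## the HETATM water never shows up in any chain
  expect_false(any(vapply(clouds, function(cl)
    any(apply(atomCoords(cl), 1L, function(p) all(p == c(9, 9, 9)))), TRUE)))
  ## altloc rule keeps exactly one copy of the duplicated atom
  alt <- parseStructure(altlocPdb())
  expect_length(alt, 1L)
  expect_equal(nAtoms(alt[[1L]]), 2L)
  expect_equal(atomCoords(alt[[1L]])[1L, ], c(0, 0, 0))
})

test_that("parseStructure errors carry context", {
  expect_error(parseStructure("REMARK nothing here\nEND"), "no ATOM records")
  bad <- paste(c(pdbLine(serial = 1L, name = "CA", x = 0, y = 0, z = 0),
                 "ATOM      2  CB AALA A   1        xx"), collapse = "\n")
  expect_error(parseStructure(bad), "line 2")
})

test_that("filterElements keeps C/H/O/N/S/Se chains and rejects others", {
  fe <- parseStructure(fePdb())[[1L]]
  rej <- filterElements(fe)
  expect_true(isRejected(rej))
  expect_equal(rej@detail, "Fe")
  allC <- AtomCloud(diag(3), c("C", "C", "C"))
  expect_identical(filterElements(allC), allC)
  withSe <- AtomCloud(rbind(c(0, 0, 0), c(1, 0, 0)), c("C", "Se"))
  expect_identical(filterElements(withSe), withSe)
  ## idempotence on the kept branch
  expect_identical(filterElements(filterElements(allC)), allC)
})

test_that("centerAtoms subtracts the coordinate mean and is idempotent", {
  cl <- AtomCloud(rbind(c(1, 0, 0), c(3, 0, 0)), c("C", "C"))
  ctr <- centerAtoms(cl)
  expect_equal(atomCoords(ctr), rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_identical(atomTypes(ctr), atomTypes(cl))
  expect_equal(atomCoords(centerAtoms(ctr)), atomCoords(ctr))
  set.seed(1)
  rnd <- AtomCloud(matrix(rnorm(30, mean = 4), 10L),
                   rep("C", 10L))
  expect_lt(sqrt(sum(colMeans(atomCoords(centerAtoms(rnd)))^2)), 1e-6)
})

test_that("synthChain is seeded, walks at 3.8 A and stays in the element set", {
  a <- synthChain(20, seed = 0)
  b <- synthChain(20, seed = 0)
  expect_identical(atomCoords(a), atomCoords(b))
  expect_identical(atomTypes(a), atomTypes(b))
  bb <- atomCoords(a)[attr(a, "backboneIdx"), ]
  steps <- sqrt(rowSums(diff(bb)^2))
  expect_true(all(abs(steps - 3.8) < 1e-6))
  m <- nAtoms(synthChain(50, seed = 1))
  expect_gte(m, 100L)
  expect_lte(m, 300L)
  for (s in 1:5)
    expect_false(isRejected(filterElements(synthChain(10, seed = s))))
  expect_error(synthChain(1), "nResidues")
})

test_that("parse -> filter -> center is deterministic", {
  run <- function() {
    cl <- parseStructure(twoChainPdb())[[1L]]
    centerAtoms(filterElements(cl))
  }
  expect_equal(atomCoords(run()), atomCoords(run()))
})

test_that("analytic fixtures have their stated geometry", {
  one <- makeFixture("single_atom", list(element = "C"))
  expect_equal(nAtoms(one), 1L)
  expect_equal(atomTypes(one)[1L, ], c(1, 0, 0, 0, 0, 0))
  two <- makeFixture("two_atoms", list(s = 1))
  expect_equal(sort(atomCoords(two)[, 1L]), c(-1, 1))
  expect_equal(atomCoords(two)[, 2:3], matrix(0, 2L, 2L))
  sph <- makeFixture("sphere_shell", list(R = 5))
  expect_true(all(abs(sqrt(rowSums(atomCoords(sph)^2)) - 5) < 1e-6))
  expect_error(makeFixture("torus"), "unknown fixture")
})
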