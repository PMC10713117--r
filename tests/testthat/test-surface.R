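test_that("smooth distance function matches its closed forms", {
  one <- makeFixture("single_atom", list(element = "C"))
  expect_equal(surfaceDistance(c(3.40, 0, 0), one), 1.70, tolerance = 1e-12)
  expect_equal(surfaceDistance(c(1.70, 0, 0), one), 0, tolerance = 1e-12)
  two <- makeFixture("two_atoms", list(s = 1))
  ## both atoms at distance 1 from the origin, r = 1.7, sigma = 0.5:
  ## -0.5 * log(2 * exp((1.7 - 1) / 0.5))
  expect_equal(surfaceDistance(c(0, 0, 0), two), -0.5 * log(2 * exp(1.4)),
               tolerance = 1e-10)
})

test_that("SDF gradient is analytic: radial case, symmetry and FD agreement", {
  one <- makeFixture("single_atom", list(element = "C"))
  expect_equal(surfaceDistanceGradient(c(2, 0, 0), one)[1L, ], c(1, 0, 0),
               tolerance = 1e-12)
  two <- makeFixture("two_atoms", list(s = 1))
  g <- surfaceDistanceGradient(c(0, 1.3, 0.4), two)
  expect_lt(abs(g[1L, 1L]), 1e-8)
  expect_error(surfaceDistanceGradient(c(0, 0, 0), one), "atom center")
  ## finite differences on 100 random queries around a synthetic chain
  chain <- synthChain(5, seed = 7)
  cfg <- SurfaceConfig()
  set.seed(11)
  q <- matrix(rnorm(300, sd = 4), 100L)
  g <- surfaceDistanceGradient(q, chain, cfg)
  h <- 1e-4
  fd <- sapply(1:3, function(k) {
    e <- matrix(0, 100L, 3L); e[, k] <- h
    (surfaceDistance(q + e, chain, cfg) -
       surfaceDistance(q - e, chain, cfg)) / (2 * h)
  })
  cosSim <- rowSums(g * fd) / (sqrt(rowSums(g^2)) * sqrt(rowSums(fd^2)))
  expect_true(all(cosSim > 0.999))
  relMag <- abs(sqrt(rowSums(g^2)) - sqrt(rowSums(fd^2))) / sqrt(rowSums(fd^2))
  expect_true(all(relMag < 1e-3))
})

test_that("surface sampling stays on the level set and respects the grid", {
  cfg <- SurfaceConfig()
  one <- makeFixture("single_atom", list(element = "C"))
  pts <- sampleSurface(one, cfg, seed = 1)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r >= 1.70 - cfg@levelTolerance &
                  r <= 1.70 + cfg@levelTolerance))
  ## grid-thinning invariant on a larger chain
  chain <- synthChain(15, seed = 3)
  pts <- sampleSurface(chain, cfg, seed = 2)
  expect_true(all(abs(surfaceDistance(pts, chain, cfg)) <= cfg@levelTolerance))
  key <- apply(floor(pts / cfg@resolution), 1L, paste, collapse = " ")
  expect_false(any(duplicated(key)))
  ## determinism
  expect_identical(pts, sampleSurface(chain, cfg, seed = 2))
})

test_that("sphere-shell surface fits a sphere within 0.2 A", {
  cfg <- SurfaceConfig()
  sph <- makeFixture("sphere_shell", list(R = 5))
  pts <- sampleSurface(sph, cfg, seed = 4)
  r <- sqrt(rowSums(pts^2))
  Rhat <- mean(r)              # least-squares radius about the origin
  expect_true(all(abs(r - Rhat) < 0.2))
})

test_that("curvature estimates recover plane and sphere closed forms", {
  cfg <- SurfaceConfig()
  ## plane: zero curvature at every scale
  xs <- seq(-8, 8, by = 1)
  plane <- as.matrix(expand.grid(xs, xs))
  plane <- cbind(plane, 0)
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(plane)), ncol = 3L)
  cp <- estimateCurvatures(plane, nrm, cfg)
  expect_equal(ncol(cp), 10L)
  expect_true(all(abs(cp) < 0.02))
  ## sphere R = 5: H = 1/R, K = 1/R^2 at the small scales
  n <- 600L
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  sp <- 5 * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  cs <- estimateCurvatures(sp, sp / 5, cfg)
  expect_true(all(abs(cs[, 1L] - 0.2) / 0.2 < 0.1))   # H at scale 1
  expect_true(all(abs(cs[, 2L] - 0.04) / 0.04 < 0.1)) # K at scale 1
  ## sign consistency and principal-curvature inequality where fits succeed
  H <- cs[, c(1, 3, 5, 7, 9)]
  K <- cs[, c(2, 4, 6, 8, 10)]
  ok <- H != 0 | K != 0
  expect_true(all((H * K)[ok] > 0))
  expect_true(all((H^2 - K)[ok] > -1e-8))
})

test_that("chemical features gather the true 16 nearest atoms", {
  cfg <- SurfaceConfig()
  chain <- synthChain(10, seed = 9)
  set.seed(13)
  pts <- matrix(rnorm(60, sd = 5), 20L)
  cf <- chemicalFeatures(pts, chain, cfg)
  expect_equal(dim(cf$features), c(20L, 16L, 7L))
  A <- atomCoords(chain)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(colSums((t(A) - pts[i, ])^2))
    ord <- order(d)[1:16]            # exhaustive sort oracle
    expect_equal(cf$idx[i, ], ord)
    expect_equal(cf$features[i, , 7L], d[ord])
    expect_true(all(diff(cf$features[i, , 7L]) >= -1e-9))
    expect_equal(unname(rowSums(cf$features[i, , 1:6])), rep(1, 16L))
  }
  ## single-atom chain: cyclic padding fills all 16 slots identically
  one <- makeFixture("single_atom", list(element = "C"))
  cf1 <- chemicalFeatures(rbind(c(1.7, 0, 0)), one, cfg)
  expect_true(all(cf1$idx == 1L))
  expect_equal(unname(cf1$features[1L, , 7L]), rep(1.7, 16L))
})

test_that("buildSurface composes the pipeline reproducibly", {
  cfg <- SurfaceConfig()
  surf <- buildSurface(synthChain(50, seed = 1), cfg, seed = 1)
  expect_s4_class(surf, "SurfaceCloud")
  expect_equal(nPoints(surf), 2048L)
  expect_equal(ncol(pointFeatures(surf)), 16L * 7L + 10L)  # 122
  expect_true(all(abs(sqrt(rowSums(surfaceNormals(surf)^2)) - 1) < 1e-6))
  ## single atom: raw surface is tiny, subsampling is with replacement
  one <- makeFixture("single_atom", list(element = "C"))
  s1 <- buildSurface(one, cfg, seed = 2)
  expect_equal(nPoints(s1), 2048L)
  r <- sqrt(rowSums(surfacePoints(s1)^2))
  expect_true(all(abs(r - 1.70) <= cfg@levelTolerance))
  ## oversize surfaces are rejected as values
  tight <- SurfaceConfig(maxPoints = 10L, targetPoints = 8L)
  rej <- buildSurface(synthChain(20, seed = 2), tight, seed = 1)
  expect_true(isRejected(rej))
  expect_equal(rej@reason, "too_many_points")
  ## bit-reproducibility
  small <- tinySurfaceConfig()
  a <- buildSurface(synthChain(12, seed = 4), small, seed = 5)
  b <- buildSurface(synthChain(12, seed = 4), small, seed = 5)
  expect_identical(surfacePoints(a), surfacePoints(b))
  expect_identical(chemRaw(a), chemRaw(b))
  expect_identical(surfaceCurvatures(a), surfaceCurvatures(b))
})
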