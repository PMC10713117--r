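## Synthetic datasets for desk-scale experiments: surface clouds from the
## synthetic chain generator, a curvature-defined binding-site task, a
## radius-defined pocket-class task, and mirrored interlocking complexes
## for PPI descriptor matching.

#' Synthetic surface-cloud dataset
#'
#' Builds `n` annotated surface clouds from [synthChain()] chains with
#' derived per-sample seeds.
#'
#' @param n Number of surfaces.
#' @param cfg A [SurfaceConfig-class].
#' @param seed Master seed.
#' @param nResidues Residues per synthetic chain (default 30).
#' @return List of [SurfaceCloud-class] objects.
#' @export
synthSurfaceDataset <- function(n, cfg = SurfaceConfig(), seed = 0L,
                                nResidues = 30L) {
  lapply(seq_len(n), function(i) {
    chain <- synthChain(nResidues, seed = deriveSeed(seed, 11L, i))
    buildSurface(chain, cfg, seed = deriveSeed(seed, 12L, i))
  })
}

#' Synthetic binding-site task
#'
#' Labels every surface point 1 iff its mean curvature at the second scale
#' exceeds the per-surface median, a geometric target that a surface
#' encoder should be able to learn.
#'
#' @inheritParams synthSurfaceDataset
#' @return List of `list(surface, labels)` entries for [finetuneSite()].
#' @export
synthSiteDataset <- function(n, cfg = SurfaceConfig(), seed = 0L,
                             nResidues = 30L) {
  surfs <- synthSurfaceDataset(n, cfg, seed, nResidues)
  lapply(surfs, function(s) {
    h2 <- surfaceCurvatures(s)[, 3L]   # H at the second scale
    list(surface = s, labels = as.integer(h2 > stats::median(h2)))
  })
}

#' Synthetic pocket-classification task
#'
#' Each class corresponds to a sphere-shell fixture radius (7 radii by
#' default), jittered per sample, so the class is determined by the
#' generative curvature scale of the surface.
#'
#' @param nPerClass Samples per class.
#' @param cfg A [SurfaceConfig-class].
#' @param seed Master seed.
#' @param radii Vector of class radii (Angstrom); its length sets the
#'   number of classes.
#' @return List of `list(surface, class)` entries for [finetunePocket()].
#' @export
synthPocketDataset <- function(nPerClass, cfg = SurfaceConfig(), seed = 0L,
                               radii = c(3, 4, 5, 6, 7, 8, 9)) {
  out <- list()
  for (cl in seq_along(radii)) {
    for (j in seq_len(nPerClass)) {
      R <- radii[cl] + withSeed(deriveSeed(seed, cl, j), runif(1, -0.2, 0.2))
      chain <- makeFixture("sphere_shell", list(R = R, spacing = 1.5))
      surf <- buildSurface(chain, cfg, seed = deriveSeed(seed, 100L + cl, j))
      out[[length(out) + 1L]] <- list(surface = surf, class = cl - 1L)
    }
  }
  out
}

#' Synthetic interlocking PPI complexes
#'
#' Each complex pairs the surface of a synthetic chain with the surface of
#' its mirror image reflected through a plane just outside the chain, so
#' the two surfaces interlock along a contact region. Positive pairs are
#' cross-surface point pairs within `contact` Angstrom.
#'
#' @param n Number of complexes.
#' @param cfg A [SurfaceConfig-class].
#' @param seed Master seed.
#' @param nResidues Residues per chain.
#' @param contact Positive-pair distance cutoff (Angstrom, default 1).
#' @param minContacts Minimum number of positive pairs per complex; the
#'   mirror plane is pushed inward until the contact patch reaches this
#'   size (default 20).
#' @return List of `list(surfaceA, surfaceB, posPairs)` entries for
#'   [finetunePpi()]; complexes that never reach a single contact pair are
#'   dropped.
#' @export
synthPpiDataset <- function(n, cfg = SurfaceConfig(), seed = 0L,
                            nResidues = 20L, contact = 1.0,
                            minContacts = 20L) {
  out <- list()
  for (i in seq_len(n)) {
    chain <- synthChain(nResidues, seed = deriveSeed(seed, 21L, i))
    surfA <- buildSurface(chain, cfg, seed = deriveSeed(seed, 22L, i))
    best <- NULL
    for (gap in seq(0, -4, by = -0.5)) {
      ## reflect the atoms through a plane near the surface's +x extreme;
      ## pushing the plane inward (negative gap) deepens the interlock
      plane <- max(surfacePoints(surfA)[, 1L]) + gap / 2
      coordsB <- atomCoords(chain)
      coordsB[, 1L] <- 2 * plane - coordsB[, 1L]
      chainB <- AtomCloud(coordsB, atomTypes(chain), chainID = "M",
                          source = "synthetic:mirror")
      surfB <- buildSurface(chainB, cfg, seed = deriveSeed(seed, 23L, i))
      D <- pairwiseSqDist(surfacePoints(surfA), surfacePoints(surfB))
      hits <- which(D <= contact^2, arr.ind = TRUE)
      if (nrow(hits) >= 1L)
        best <- list(surfaceA = surfA, surfaceB = surfB,
                     posPairs = unname(hits))
      if (nrow(hits) >= minContacts) break
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}
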