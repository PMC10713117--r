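## Structure ingestion: PDB text -> per-chain AtomClouds, element filtering,
## centering, and the synthetic chain / analytic fixture generators.

## Infer an element symbol from a PDB atom name when the element column is
## blank. Digits and primes are stripped; a leading "SE" wins over "S";
## names like "1HB" are hydrogens.
.inferElement <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nzchar(nm)) return(NA_character_)
  if (startsWith(nm, "SE")) return("Se")
  substr(nm, 1L, 1L)
}

## Normalize an element string from the PDB element column ("SE" -> "Se").
.normalizeElement <- function(el) {
  el <- trimws(el)
  if (!nzchar(el)) return(NA_character_)
  paste0(toupper(substr(el, 1L, 1L)),
         tolower(substr(el, 2L, nchar(el))))
}

#' Parse a PDB structure into per-chain atom clouds
#'
#' Decomposes PDB-format text into one uncentered [AtomCloud-class] per
#' chain. Only `ATOM` records are used (`HETATM`, waters and ligands are
#' ignored), alternate locations other than blank or `'A'` are dropped, and
#' only the first model of a multi-model file is read. The element is taken
#' from the element column, falling back to inference from the atom name.
#'
#' @param pdbText Character scalar (or vector of lines) of PDB-format text.
#' @param source Provenance label recorded in each cloud.
#' @return List of [AtomCloud-class] objects, one per distinct chain id, in
#'   order of first appearance. Elements outside C,H,O,N,S,Se are kept here
#'   (with their symbol recorded); [filterElements()] applies the element
#'   filter.
#' @export
parseStructure <- function(pdbText, source = "pdb") {
  lines <- if (length(pdbText) == 1L) strsplit(pdbText, "\n", fixed = TRUE)[[1L]]
           else as.character(pdbText)
  isAtom <- startsWith(lines, "ATOM")
  if (!any(isAtom)) stop("empty structure: no ATOM records found")
  ## Pre-scan for malformed ATOM records so errors carry a line number
  ## (the bio3d reader does not report them).
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("unparseable ATOM record at line %d: too short", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("unparseable ATOM record at line %d: bad coordinates", i))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records found")
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  at <- at[keep, , drop = FALSE]
  el <- vapply(seq_len(nrow(at)), function(i) {
    e <- at$elesy[i]
    e <- if (is.null(e) || is.na(e)) "" else e
    e <- .normalizeElement(e)
    if (is.na(e)) e <- .inferElement(at$elety[i])
    if (is.na(e)) stop("cannot determine element for atom ", at$eleno[i])
    e
  }, character(1))
  chains <- unique(at$chain)
  lapply(chains, function(ch) {
    sel <- at$chain == ch
    coords <- cbind(at$x[sel], at$y[sel], at$z[sel])
    known <- el[sel] %in% elementOrder()
    types <- matrix(0, sum(sel), 6L)
    types[cbind(seq_len(sum(sel)),
                ifelse(known, match(el[sel], elementOrder()), 1L))] <- 1
    cloud <- AtomCloud(coords, types, chainID = as.character(ch),
                       source = source)
    ## keep the true symbols around for filterElements on exotic atoms
    attr(cloud, "elements") <- el[sel]
    cloud
  })
}

#' Filter a chain by its element composition
#'
#' A chain is kept unchanged iff every atom is one of C, H, O, N, S, Se;
#' otherwise a [Rejection-class] naming the first offending element is
#' returned. Idempotent.
#'
#' @param chain An [AtomCloud-class].
#' @return The chain, or a [Rejection-class] with reason `"element"`.
#' @export
filterElements <- function(chain) {
  stopifnot(is(chain, "AtomCloud"))
  els <- attr(chain, "elements")
  if (is.null(els)) els <- elementSymbols(chain)
  bad <- setdiff(unique(els), elementOrder())
  if (length(bad)) Rejection("element", bad[1L]) else chain
}

#' Center a chain's coordinates on their mean
#'
#' @param chain An [AtomCloud-class].
#' @return The chain with `mean(coords) = 0` (types unchanged). Idempotent.
#' @export
centerAtoms <- function(chain) {
  stopifnot(is(chain, "AtomCloud"))
  ctr <- colMeans(chain@coords)
  out <- chain
  out@coords <- sweep(chain@coords, 2L, ctr)
  out
}

#' Generate a synthetic protein-like chain
#'
#' Builds a deterministic pseudo-chain: the backbone is a self-avoiding
#' random walk with exactly 3.8 Angstrom steps (the C-alpha virtual bond
#' length), and each residue carries 1-4 pseudo side-chain atoms within
#' 2.5 Angstrom of its backbone atom. Elements are drawn from C,H,O,N,S,Se
#' with C/N/O dominant, so the chain always passes [filterElements()].
#' The output is centered.
#'
#' @param nResidues Number of residues (>= 2).
#' @param seed Integer seed; fixed seeds give bit-identical clouds.
#' @return A centered [AtomCloud-class].
#' @export
synthChain <- function(nResidues, seed = 0L) {
  if (nResidues < 2L) stop("nResidues must be >= 2")
  withSeed(seed, {
    step <- 3.8
    minSep <- 3.0   # self-avoidance radius between non-adjacent CA atoms
    bb <- matrix(0, nResidues, 3L)
    dir <- c(1, 0, 0)
    for (i in 2:nResidues) {
      placed <- FALSE
      for (tries in 1:50) {
        ## propose a direction correlated with the previous one (persistence
        ## gives a globular-but-extended walk rather than a dense ball)
        prop <- dir + rnorm(3L, sd = 0.8)
        prop <- prop / sqrt(sum(prop^2))
        cand <- bb[i - 1L, ] + step * prop
        if (i <= 3L ||
            min(sqrt(rowSums(sweep(bb[1:(i - 2L), , drop = FALSE], 2L,
                                   cand)^2))) >= minSep) {
          bb[i, ] <- cand
          dir <- prop
          placed <- TRUE
          break
        }
      }
      if (!placed) {  # fall back: accept the last proposal
        bb[i, ] <- cand
        dir <- prop
      }
    }
    coords <- list()
    els <- list()
    bbIdx <- integer(nResidues)
    sideEls <- c("C", "H", "O", "N", "S", "Se")
    sideProb <- c(0.40, 0.25, 0.15, 0.15, 0.04, 0.01)
    for (i in seq_len(nResidues)) {
      coords[[length(coords) + 1L]] <- bb[i, ]
      bbIdx[i] <- length(coords)
      els[[length(els) + 1L]] <- "C"          # backbone carbon
      nSide <- sample.int(4L, 1L)
      for (s in seq_len(nSide)) {
        u <- rnorm(3L)
        u <- u / sqrt(sum(u^2))
        r <- runif(1L, 0.8, 2.5)
        coords[[length(coords) + 1L]] <- bb[i, ] + r * u
        els[[length(els) + 1L]] <- sample(sideEls, 1L, prob = sideProb)
      }
    }
    cloud <- AtomCloud(do.call(rbind, coords), unlist(els),
                       chainID = "S", source = sprintf("synthetic(seed=%d)", seed))
    cloud <- centerAtoms(cloud)
    attr(cloud, "backboneIdx") <- bbIdx   # which atoms form the 3.8 A walk
    cloud
  })
}

#' Analytic atom-cloud fixtures
#'
#' Small deterministic clouds with known surface geometry, used to check the
#' surface pipeline against closed forms: a single atom (spherical surface),
#' two atoms at (+/-s, 0, 0), a shell of small atoms tiling a sphere of
#' radius R (surface approximates a sphere), and a slab of atoms tiling a
#' plane patch (surface approximates a plane).
#'
#' @param kind One of `"single_atom"`, `"two_atoms"`, `"sphere_shell"`,
#'   `"plane_slab"`.
#' @param params Named list of numbers: `element` (default "C"), `s`
#'   (two_atoms half-separation, default 1), `R` (sphere radius, default 5),
#'   `spacing` (tiling spacing; default 0.6 for the sphere shell so the
#'   tiling is dense enough to close the interior cavity and smooth the
#'   outer level set into a single sphere, 1 for the plane slab),
#'   `halfWidth` (plane half width, default 6).
#' @return An [AtomCloud-class] (uncentered; fixtures are built about the
#'   origin by construction).
#' @export
makeFixture <- function(kind, params = list()) {
  el <- params$element %||% "C"
  switch(kind,
    single_atom = AtomCloud(matrix(0, 1L, 3L), el, chainID = "F",
                            source = "fixture:single_atom"),
    two_atoms = {
      s <- params$s %||% 1
      AtomCloud(rbind(c(s, 0, 0), c(-s, 0, 0)), c(el, el), chainID = "F",
                source = "fixture:two_atoms")
    },
    sphere_shell = {
      R <- params$R %||% 5
      spacing <- params$spacing %||% 0.6
      pts <- .fibonacciSphere(max(16L, ceiling(4 * pi * R^2 / spacing^2)))
      AtomCloud(R * pts, rep(el, nrow(pts)), chainID = "F",
                source = "fixture:sphere_shell")
    },
    plane_slab = {
      hw <- params$halfWidth %||% 6
      spacing <- params$spacing %||% 1
      xs <- seq(-hw, hw, by = spacing)
      gridXY <- as.matrix(expand.grid(x = xs, y = xs))
      coords <- cbind(gridXY, 0)
      dimnames(coords) <- NULL
      AtomCloud(coords, rep(el, nrow(coords)), chainID = "F",
                source = "fixture:plane_slab")
    },
    stop("unknown fixture kind: ", kind)
  )
}

## Deterministic near-uniform points on the unit sphere (Fibonacci lattice).
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
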