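## Per-chain surface feature cache. Logical schema: groups
## surface/{points,normals,curvatures,chem_raw,chem_neighbor_idx} and
## atoms/{coords,types}, with config_json, seed and schema_version
## attributes; serialized as a single RDS container per chain.

.cacheSchemaVersion <- 1L

#' Write a surface cloud to a cache file
#'
#' @param cloud A [SurfaceCloud-class].
#' @param path Output file path.
#' @param atoms Optional [AtomCloud-class] stored alongside the surface.
#' @return `path`, invisibly.
#' @export
writeSurfaceCache <- function(cloud, path, atoms = NULL) {
  stopifnot(is(cloud, "SurfaceCloud"))
  cfg <- cloud@config
  obj <- list(
    schema_version = .cacheSchemaVersion,
    surface = list(points = cloud@points, normals = cloud@normals,
                   curvatures = cloud@curvatures, chem_raw = cloud@chemRaw,
                   chem_neighbor_idx = cloud@chemNeighborIdx),
    atoms = if (is.null(atoms)) NULL
            else list(coords = atomCoords(atoms), types = atomTypes(atoms),
                      chain_id = chainID(atoms)),
    config_json = jsonlite::toJSON(list(
      smoothing_sigma = cfg@smoothingSigma, resolution = cfg@resolution,
      level_tolerance = cfg@levelTolerance, target_points = cfg@targetPoints,
      max_points = cfg@maxPoints, curvature_scales = cfg@curvatureScales,
      n_chem_neighbors = cfg@nChemNeighbors, vdw_radii = as.list(cfg@vdwRadii)),
      auto_unbox = TRUE, digits = NA),
    seed = cloud@seed,
    chain_id = cloud@chainID)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a surface cloud from a cache file
#'
#' Bit-identical round-trip of everything written by
#' [writeSurfaceCache()]; missing datasets or a schema-version mismatch
#' raise a schema error.
#'
#' @param path Cache file path.
#' @return List with `surface` (a [SurfaceCloud-class]) and `atoms` (an
#'   [AtomCloud-class] or NULL).
#' @export
readSurfaceCache <- function(path) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$schema_version, .cacheSchemaVersion))
    stop("schema error: cache schema version mismatch")
  need <- c("points", "normals", "curvatures", "chem_raw", "chem_neighbor_idx")
  if (is.null(obj$surface) || !all(need %in% names(obj$surface)))
    stop("schema error: missing dataset in surface group")
  cj <- jsonlite::fromJSON(obj$config_json)
  cfg <- SurfaceConfig(smoothingSigma = cj$smoothing_sigma,
                       resolution = cj$resolution,
                       levelTolerance = cj$level_tolerance,
                       targetPoints = cj$target_points,
                       maxPoints = cj$max_points,
                       curvatureScales = cj$curvature_scales,
                       nChemNeighbors = cj$n_chem_neighbors,
                       vdwRadii = unlist(cj$vdw_radii))
  surf <- new("SurfaceCloud", points = obj$surface$points,
              normals = obj$surface$normals,
              curvatures = obj$surface$curvatures,
              chemRaw = obj$surface$chem_raw,
              chemNeighborIdx = obj$surface$chem_neighbor_idx,
              config = cfg, seed = obj$seed, chainID = obj$chain_id)
  atoms <- if (is.null(obj$atoms)) NULL
           else AtomCloud(obj$atoms$coords, obj$atoms$types,
                          chainID = obj$atoms$chain_id, source = path)
  list(surface = surf, atoms = atoms)
}

#' Append a record to a JSONL log
#'
#' @param record Named list; one JSON object per line, append-only.
#' @param path Log file path.
#' @return `path`, invisibly.
#' @export
appendLog <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
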