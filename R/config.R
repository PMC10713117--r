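## Run configuration: nested YAML config with validated defaults, plus
## checkpoint serialization (weights archive + JSON sidecar).

.runConfigDefaults <- function() {
  list(
    surface = list(smoothing_sigma = 0.5, resolution = 1.0,
                   level_tolerance = 0.05, target_points = 2048L,
                   max_points = 20000L,
                   curvature_scales = c(1, 2, 3, 5, 10),
                   n_chem_neighbors = 16L),
    patches = list(g = 128L, k_prime = 32L, m = 0.6),
    model = list(d = 384L, encoder_depth = 12L, encoder_heads = 6L,
                 decoder_depth = 4L, decoder_heads = 6L, mlp_ratio = 4,
                 n_classes = 7L, descriptor_dim = 64L),
    training = list(lr = 1e-3, batch = 16L, epochs = 50L,
                    weight_decay = 0.01, schedule = "constant",
                    finetune_lr = 1e-4, finetune_epochs = 50L),
    seed = 0L,
    paths = list(cache_dir = "cache", out_dir = "out")
  )
}

.validateKeys <- function(cfg, defaults, path = "") {
  for (nm in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[nm]])) {
      if (!is.list(cfg[[nm]]) && !is.null(cfg[[nm]]))
        stop("type mismatch for config key: ", full)
      .validateKeys(cfg[[nm]], defaults[[nm]], full)
    } else if (!is.null(cfg[[nm]])) {
      if (is.numeric(defaults[[nm]]) && !is.numeric(cfg[[nm]]))
        stop("type mismatch for config key: ", full)
      if (is.character(defaults[[nm]]) && !is.character(cfg[[nm]]))
        stop("type mismatch for config key: ", full)
    }
  }
}

.mergeDefaults <- function(cfg, defaults) {
  out <- defaults
  for (nm in names(cfg)) {
    out[[nm]] <- if (is.list(defaults[[nm]]))
      .mergeDefaults(cfg[[nm]], defaults[[nm]]) else cfg[[nm]]
  }
  out
}

.checkRanges <- function(cfg) {
  if (cfg$patches$m < 0 || cfg$patches$m >= 1)
    stop("config value out of range: m must be in [0, 1)")
  if (cfg$surface$resolution <= 0)
    stop("config value out of range: resolution must be > 0")
  if (cfg$surface$smoothing_sigma <= 0)
    stop("config value out of range: smoothing_sigma must be > 0")
  if (cfg$model$d %% cfg$model$encoder_heads != 0)
    stop("config value out of range: d must be divisible by encoder_heads")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads YAML (path or literal text), validates every key against the
#' known schema (unknown keys and type mismatches are errors naming the
#' key), fills defaults (sigma 0.5 A, resolution 1 A, 2048 points, scales
#' 1/2/3/5/10 A, 16 chemical neighbors, m = 0.6, lr 1e-3, batch 16, 50
#' epochs) and range-checks the result.
#'
#' @param pathOrText Path to a YAML file, or YAML text.
#' @return Nested named list (the run configuration).
#' @export
loadRunConfig <- function(pathOrText = "") {
  cfg <- if (file.exists(pathOrText)) yaml::read_yaml(pathOrText)
         else yaml::yaml.load(pathOrText)
  if (is.null(cfg)) cfg <- list()
  defaults <- .runConfigDefaults()
  .validateKeys(cfg, defaults)
  .checkRanges(.mergeDefaults(cfg, defaults))
}

#' Save a run configuration to YAML
#'
#' Round-trips losslessly with [loadRunConfig()].
#'
#' @param cfg A run configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## Expand a run configuration into the typed config objects.
.surfaceConfigFrom <- function(cfg) {
  SurfaceConfig(smoothingSigma = cfg$surface$smoothing_sigma,
                resolution = cfg$surface$resolution,
                levelTolerance = cfg$surface$level_tolerance,
                targetPoints = cfg$surface$target_points,
                maxPoints = cfg$surface$max_points,
                curvatureScales = cfg$surface$curvature_scales,
                nChemNeighbors = cfg$surface$n_chem_neighbors)
}

.modelConfigFrom <- function(cfg) {
  ModelConfig(d = cfg$model$d, encoderDepth = cfg$model$encoder_depth,
              encoderHeads = cfg$model$encoder_heads,
              decoderDepth = cfg$model$decoder_depth,
              decoderHeads = cfg$model$decoder_heads,
              mlpRatio = cfg$model$mlp_ratio, g = cfg$patches$g,
              kPrime = cfg$patches$k_prime, m = cfg$patches$m,
              nClasses = cfg$model$n_classes,
              descriptorDim = cfg$model$descriptor_dim)
}

#' Save a model checkpoint
#'
#' Writes the weight archive (`<path>.rds`) and a JSON sidecar
#' (`<path>.json`) recording the model configuration, seeds and an
#' optional loss curve.
#'
#' @param model An [MAEModel-class].
#' @param path Path stem (without extension).
#' @param state Optional [TrainState-class] whose loss curve is recorded.
#' @param surfaceConfig Optional [SurfaceConfig-class] to record.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path, state = NULL, surfaceConfig = NULL) {
  saveRDS(model@params, paste0(path, ".rds"))
  cfg <- model@config
  side <- list(
    schema_version = 1L,
    model = list(d = cfg@d, encoder_depth = cfg@encoderDepth,
                 encoder_heads = cfg@encoderHeads,
                 decoder_depth = cfg@decoderDepth,
                 decoder_heads = cfg@decoderHeads, mlp_ratio = cfg@mlpRatio,
                 g = cfg@g, k_prime = cfg@kPrime, m = cfg@m,
                 n_classes = cfg@nClasses,
                 descriptor_dim = cfg@descriptorDim),
    init_seed = model@initSeed)
  if (!is.null(state))
    side$pretraining <- list(loss_curve = state@epochLosses,
                             best_epoch = state@bestEpoch,
                             seed = state@seed)
  if (!is.null(surfaceConfig))
    side$surface <- list(smoothing_sigma = surfaceConfig@smoothingSigma,
                         resolution = surfaceConfig@resolution,
                         target_points = surfaceConfig@targetPoints)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path stem used in [saveCheckpoint()].
#' @return An [MAEModel-class].
#' @export
loadCheckpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- side$model
  cfg <- ModelConfig(d = m$d, encoderDepth = m$encoder_depth,
                     encoderHeads = m$encoder_heads,
                     decoderDepth = m$decoder_depth,
                     decoderHeads = m$decoder_heads, mlpRatio = m$mlp_ratio,
                     g = m$g, kPrime = m$k_prime, m = m$m,
                     nClasses = m$n_classes, descriptorDim = m$descriptor_dim)
  params <- readRDS(paste0(path, ".rds"))
  new("MAEModel", config = cfg, params = params,
      initSeed = as.integer(side$init_seed))
}
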