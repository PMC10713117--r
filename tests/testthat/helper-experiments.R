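## Lazily memoised desk-scale experiments, shared between the module tests
## and the acceptance suite so each expensive run happens once per session.

.expCache <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (is.null(.expCache[[key]])) .expCache[[key]] <- build()
  .expCache[[key]]
}

expSurfaces8 <- function() .memo("surf8", function()
  synthSurfaceDataset(8, tinySurfaceConfig(), seed = 0, nResidues = 30L))

## Masked pretraining on 8 synthetic chains, 30 epochs, per-sample steps.
expPretrain <- function() .memo("pretrain", function()
  pretrain(expSurfaces8(), tinyModelConfig(),
           settings = list(epochs = 30L, batch = 1L), seed = 0))

## Single-sample overfit: 200 steps with a step size suited to the budget.
expOverfit <- function() .memo("overfit", function() {
  surfs <- synthSurfaceDataset(1, tinySurfaceConfig(), seed = 5)
  pretrain(surfs, tinyModelConfig(),
           settings = list(epochs = 200L, batch = 1L, lr = 1e-2), seed = 0)
})

expSiteData <- function() .memo("siteData", function()
  synthSiteDataset(64, tinySurfaceConfig(), seed = 3))

## Site fine-tuning from the pretrained best checkpoint.
expSiteFinetune <- function() .memo("siteFT", function()
  finetuneSite(expSiteData(), expPretrain()$best,
               settings = list(epochs = 20L, lr = 1e-3), seed = 1))

## Same task and budget from a random initialization (scratch baseline).
expSiteScratch <- function() .memo("siteScratch", function()
  finetuneSite(expSiteData(), maeModel(tinyModelConfig(), seed = 42),
               settings = list(epochs = 20L, lr = 1e-3), seed = 1))
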