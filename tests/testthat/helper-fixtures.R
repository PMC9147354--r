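# Shared fixtures, cached for the duration of one test run so the expensive
# desk-scale learning experiment is trained once and reused by every test
# that needs a trained model.

.fixtureCache <- new.env(parent = emptyenv())

# The desk-scale learning experiment: 100 phantom pairs at 96 x 160,
# 80 train / 20 validation, U-Net levels=3 base=8, 10 epochs, batch 1,
# Adam, learning-rate schedule 0.3 per 10 epochs.
deskLearningFixture <- function() {
  if (!is.null(.fixtureCache$desk)) return(.fixtureCache$desk)
  pairs <- deskDataset(100, seed = 20240101L)
  split <- splitDataset(100, 0.8, seed = 20240102L)
  model <- buildModel(deskArchitectureSpec("unet"), seed = 20240103L)
  fit <- trainModel(model, pairs[split@train], pairs[split@val],
                    deskTrainConfig(seed = 20240104L))
  .fixtureCache$desk <- list(pairs = pairs, split = split, fit = fit)
  .fixtureCache$desk
}

# A quick 3-epoch training run on 16 desk pairs, for tests that only need
# "some trained model" rather than the full criterion-level experiment.
miniFitFixture <- function() {
  if (!is.null(.fixtureCache$mini)) return(.fixtureCache$mini)
  pairs <- deskDataset(16, seed = 424242L)
  model <- buildModel(deskArchitectureSpec("unet"), seed = 7L)
  cfg <- trainConfig(initialLr = 2e-3, epochs = 3L, seed = 9L)
  fit <- trainModel(model, pairs[1:12], pairs[13:16], cfg)
  .fixtureCache$mini <- list(pairs = pairs, fit = fit)
  .fixtureCache$mini
}
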