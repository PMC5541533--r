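# Shared small synthetic scenes for module tests, generated once per run.
# Reduced frames keep module tests fast; the acceptance suite uses the
# default (larger) study-condition scenes.

.sceneCache <- new.env(parent = emptyenv())

cachedScene <- function(key, specFn) {
  if (is.null(.sceneCache[[key]])) .sceneCache[[key]] <- generateScene(specFn)
  .sceneCache[[key]]
}

# Full-size frame (the chain's parameter scales assume it) but a single
# focus, for determinate zone counts.
smallWidefieldSpec <- function(seed = 1, ...) {
  sceneSpec("widefield", seed = seed, nFoci = 1,
            focusRadiiUm = c(35, 50), nVeins = 2, veinRadiiUm = c(30, 50),
            ...)
}

smallNarrowfieldSpec <- function(seed = 1, ...) {
  sceneSpec("narrowfield", seed = seed, size = c(384L, 512L),
            focusRadiiUm = c(24, 32), ...)
}

smallNarrowfieldParams <- function(...) {
  narrowfieldParams(frameScale = 512 / 5184, ...)
}

# Analysis-scale ground truth for a widefield scene.
downscaledTruth <- function(scene) {
  m <- downscaleQuarter(focusMask(scene) + 0.0)
  matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
}

downscaledVeinTruth <- function(scene) {
  m <- downscaleQuarter(veinMask(scene) + 0.0)
  matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
}
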