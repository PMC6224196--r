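# Shared fixtures: small, fast synthetic scenes built in code.

# a compact scene for structural tests (5 cells, coarse pixels)
tinyScene <- function(seed = 1, ...) {
  renderScene(tinyConfig(seed = seed, ...))
}

tinyConfig <- function(seed = 1, nCells = 5, pixelSize = 0.4, ...) {
  sceneConfig(nCells = nCells, pixelSize = pixelSize, seed = seed, ...)
}

# the scene family used for recovery tests: configured exponential with
# known decay length, mean-projected band profiles for trend fitting
recoveryConfig <- function(seed, lambda = 20, sd = 0, ...) {
  sceneConfig(nCells = 12, seed = seed,
              gradient = list(Cmax = 100, lambda = lambda,
                              background = 0),
              noise = list(gaussian_sd = sd, poisson = sd > 0,
                           psf_sigma = 0.3), ...)
}

# scene with one marked clone spanning cells 4-6
cloneConfig <- function(seed, uptake = 1, ...) {
  sceneConfig(nCells = 12, seed = seed,
              gradient = list(Cmax = 100, lambda = 30, background = 0),
              clones = list(list(cells = 4:6, uptake_factor = uptake,
                                 label_channel = "clone")), ...)
}

measuredCloneRatio <- function(seed, uptake = 1) {
  sc <- renderScene(cloneConfig(seed, uptake))
  ratioOutIn(cloneRatio(getChannel(sc, "ligand"), sceneCloneMask(sc),
                        sceneControlMask(sc), pixelSize = sc@pixelSize))
}
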