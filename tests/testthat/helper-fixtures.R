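# Shared fixture builders (everything generated in code; no stored data).

# A flat-colour image.
flatImage <- function(h = 8, w = 12, rgb = c(100, 200, 50), id = "p01",
                      time = 5) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  NsrImage(px, id, time)
}

randomMask <- function(h = 16, w = 24, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# Render + preprocess one synthetic photograph to the model grid.
prepOne <- function(aNorm = c(0.2, 0.16, 0.09, 0.004), seed = 11,
                    distance = NULL, cast = NULL,
                    spec = calibrationSpec()) {
  rend <- renderImage(aNorm, "HC001", 5, distance = distance, cast = cast,
                      seed = seed)
  preprocessImage(rend$image, rend$labelMask, rend$flushMask, spec = spec)
}

# Seeded label permutation for null-distribution checks.
withSeedPerm <- function(seed, y) {
  set.seed(seed + 5000)
  factor(sample(as.character(y)), levels = levels(y))
}

# Small hyperparameter grid for harness-level statistical tests, where the
# protocol (not the grid breadth) is under test.
smallGrid <- function() {
  hyperGrid(kernels = "rbf", C = c(0.1, 1), gamma = c(0.01, 0.1),
            smoteK = 5)
}
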