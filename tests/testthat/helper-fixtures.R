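# Shared fixture builders. Everything is generated in code; no binary files.

# Published release constants (percent/hour convention) used as generating
# truth in recovery tests.
releaseTruth <- list(
  zero_order       = c(K0 = 0.166),
  first_order      = c(K1 = 0.002),
  higuchi          = c(KH = 2.300),
  korsmeyer_peppas = c(KP = 1.192, n = 0.650)
)

# Printed group summaries (bcl-2 / cox-2 chromogen abundance, EU/pixel).
bcl2Summaries <- data.frame(
  label = c("C_BCNU@HCLI", "Cream BCNU", "Base Cream", "Control Saline"),
  mean = c(75.63, 106.33, 185.66, 157),
  sd = c(23.59, 15.12, 59.33, 45.15),
  n = 7)
cox2Summaries <- data.frame(
  label = c("C_BCNU@HCLI", "Cream BCNU", "Base Cream", "Control Saline"),
  mean = c(67.41, 106.86, 159.46, 223),
  sd = c(18.70, 20.63, 54.26, 80.23),
  n = 7)

# A KineticFit shell with a prescribed R^2, for model-selection tests.
fitShell <- function(model, r2) {
  k <- switch(model,
              zero_order = c(K0 = 1), first_order = c(K1 = 1),
              higuchi = c(KH = 1), korsmeyer_peppas = c(KP = 1, n = 1))
  new("KineticFit", model = model, constants = k, rSquared = r2,
      residuals = numeric(0), fitted = numeric(0))
}

# Random 8-bit RGB image for fuzz tests.
randomRgbImage <- function(h, w, seed) {
  set.seed(seed)
  RgbImage(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

# DAB intensity matrix wrapped so zoneHistogram/chromogenEnergy accept it.
dabMatrix <- function(values, h, w) matrix(values, h, w)
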