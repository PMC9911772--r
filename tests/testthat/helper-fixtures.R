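# Shared fixtures: canonical grid, a reference truth record/triple, and a
# five-component table with comfortably separated, mid-scale amplitudes.

fixtureGrid <- function() defaultGrid()

fixtureComponents <- function(amplitude = c(0.30, 0.25, 0.12, 0.28, 0.15),
                              width = c(20, 7, 6, 5, 25)) {
  data.frame(center = sort(unname(peakCenters)),
             amplitude = amplitude, width = width)
}

fixtureTruth <- function(hb = 14, tsb = 8, spo2 = 97, sigma = 0,
                         seed = 42L, ...) {
  truthRecord(BloodPanel(hb, tsb, spo2), sigma = sigma, seed = seed, ...)
}

fixtureTriple <- function(...) generateSpectrum(fixtureTruth(...))

noBoxcarConfig <- function(...) {
  hemospecConfig(boxcar = list(width = 0L), ...)
}
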