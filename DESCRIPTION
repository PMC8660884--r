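Package: caflits
Title: Quantitative Calcium Imaging with Frequency-Domain FLIM and a
    Two-State Lifetime Biosensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts frequency-domain fluorescence-lifetime (FD-FLIM)
    phase stacks recorded from a two-state calcium biosensor into absolute
    intracellular calcium concentrations. Implements first-harmonic
    demodulation of homodyne phase stacks, reference-fluorophore
    calibration, background correction, phasor (polar plot) conversion,
    projection of pixel phasors onto the chord between the calcium-free
    and calcium-bound endpoints, intensity-ratio correction of the line
    fraction to molecular bound fraction, and conversion to concentration
    through a Hill calibration. Also provides the sensor-characterization
    math: Hill fits to titrations, equilibrium extraction from
    permeabilization time series, detection-range estimation, relative
    quantum yield from dilution-series spectra, extinction coefficients
    via alkali denaturation, one- and two-site pH models with
    dynamic-range curves, magnesium-sensitivity ratios and plate-reader
    normalization. A synthetic-data module generates every input the
    pipeline consumes from a packaged ground-truth sensor model, so all
    stages are testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
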