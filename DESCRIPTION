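Package: lungtau
Title: Regional Expiratory Time Constants from Dynamic 4DCT Lung Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise analysis of lung deaeration dynamics during passive
    exhalation from registered four-dimensional computed tomography (4DCT)
    image sequences. Fits a single-exponential decay model to the
    time-varying CT density of every lung voxel during expiration, yielding
    maps of initial density, equilibrium density, and deaeration time
    constants with F-test significance filtering. Computes
    Jacobian-determinant based specific air volume change (SACJ) and its
    time constants, Hounsfield-unit aeration classification, gravitational
    height profiles, parametric response maps, whole-lung mechanical time
    constants, and dynamic elastance from ventilator waveforms. Includes a
    synthetic 4D lung phantom generator with analytic ground truth so the
    entire pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    minpack.lm
Config/testthat/edition: 3
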