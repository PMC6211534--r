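Package: aerotrack
Title: Tracking, Sizing and Beam Diagnostics for Focused Aerosol Nanoparticle Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for Rayleigh-scattering microscopy of focused
    aerosol beams of nanoparticles, as used to characterize aerodynamic-lens
    sample injectors for single-particle X-ray imaging. Detects particle
    spots in double-exposure microscope frames with a difference-of-Gaussians
    filter, pairs the two flash images of each particle to measure velocities,
    sizes particles from their integrated scattering brightness via the
    Rayleigh d^6 law, characterizes the particle beam (Gaussian-beam envelope,
    pressure scaling laws, areal density, injection yield, predicted hit
    ratio), and models particle acceleration in the free-jet expansion at the
    injector exit (centerline Mach correlation, isentropic gas states,
    Henderson sphere drag, Stokes-number velocity collapse). A seeded
    synthetic-frame simulator reproduces the instrument's photometry and
    noise so that every pipeline stage can be tested without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
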