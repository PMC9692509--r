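Package: magnasal
Title: Magnetophoretic Microparticle Transport in a Nasal Airway Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for magnetically assisted nose-to-brain drug
    delivery. Provides closed-form (Coulombian) magnetic fields and field
    gradients of uniformly magnetized cuboid permanent magnets, a steady
    incompressible laminar flow solver on a parameterized two-dimensional
    sagittal nasal-passage surrogate, Lagrangian tracing of magnetite
    microparticles under Stokes drag and magnetophoretic force, and
    delivery-efficiency accounting for the olfactory region under three
    permanent-magnet placement protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
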