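Package: loopscope
Title: Closed-Loop Optogenetic Microscopy: Scheduling, Patterned
    Stimulation and Feedback Control with a Simulated Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for closed-loop light microscopy experiments in
    which imaging, nuclear segmentation, and patterned optogenetic
    stimulation are sequenced by a master scheduler across multipoint
    acquisitions. Experiments are declared in plain TOML configuration
    files plus an XML stage-position list; stimulation rules include
    traveling bar waves, per-cell Voronoi gradient ("vortex") patterns,
    and bang-bang feedback control of single-cell fluorescence against
    scalar or image-valued set points. A fully simulated microscope
    backend (agent cells that polarize and migrate along illumination
    gradients, a reversible photochromic fluorophore, and a synthetic
    nuclear-image renderer) makes the entire loop runnable and testable
    without hardware. Post-hoc analysis covers centroid tracking,
    wave-phase-binned velocities, polar decomposition of tissue flows
    and coefficient-of-variation time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    xml2,
    stats,
    utils,
    grDevices,
    tools,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
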