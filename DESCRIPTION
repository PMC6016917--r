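Package: coferm
Title: Kinetic Modeling of Cellobiose and Xylose Co-Fermentation by
    Engineered Yeast Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Batch fermentation kinetics for engineered Saccharomyces
    cerevisiae specialist strains and their co-culture. Implements
    Monod-type growth models with Haldane (Andrews) substrate inhibition
    and Luong ethanol inhibition for a cellobiose-consuming strain (EJ2)
    and a xylose-consuming strain (SR8), a coupled co-culture model with
    empirical weighing factors, adaptive and fixed-step ODE simulation,
    Lineweaver-Burk initialization and least-squares parameter estimation,
    a synthetic fermentation data generator, and an inoculum-design
    workflow for simultaneous mixed-sugar utilization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
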