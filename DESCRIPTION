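Package: peroxidyn
Title: Kinetic Modelling of Hydrogen Peroxide Stress in Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the coupled dynamics of internal and external hydrogen
    peroxide and superoxide in E. coli populations: endogenous ROS production,
    Michaelis-Menten scavenging by alkyl hydroperoxide reductase (Ahp) and
    catalase (Cat), passive membrane diffusion, and logistic cell growth with a
    post-stress lag. Provides stiff ODE integration of the full nonlinear
    model for one or several strains sharing a medium, closed-form
    bi-exponential solutions of the linearised low- and high-concentration
    regimes (eigenvalues, steady states, plateaus, time and height of the
    internal peak, external half-lives, scavenger contribution fractions), and
    dose metrics such as the maximal and cumulative internal hydrogen peroxide
    exposure. Includes a scenario registry for classic whole-cell and
    cell-extract detoxification experiments and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
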