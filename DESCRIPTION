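Package: impactchain
Title: Lumped-Parameter Simulation of Surgical Impaction Force Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the one-dimensional transmission of a surgical mallet
    blow through the instrument chain used to assemble femoral head taper
    junctions (mallet, impactor, polymer tip, head, stem, responding tissue).
    The chain is a serial spring-mass-damper model with a one-sided hard-stop
    contact at the impactor tip and a Coulomb stick-slip friction element with
    displacement-dependent normal force at the taper junction, integrated as a
    stiff ODE system with a compiled right-hand side. Includes a synthetic
    mallet-pulse generator, zero-phase Butterworth signal conditioning and
    feature extraction (normalized peaks, periods, delays, windowed RMSE),
    Monte-Carlo sensitivity screening, bounded least-squares parameter
    estimation against measured or pseudo-measured force traces, and the
    impactor and tissue extrapolation sweeps, so that forces at positions that
    cannot host a sensor can be estimated from the applied mallet pulse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
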