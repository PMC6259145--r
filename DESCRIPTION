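Package: saforge
Title: Reaction Yield and Specific Radioactivity Assessment for
    Reactor-Produced Radioisotopes
Version: 0.1.0
Authors@R:
    person("saforge", "maintainers", email = "saforge@example.org",
           role = c("aut", "cre"))
Description: Closed-form modelling of radioisotope production in a nuclear
    reactor: target burn-up under thermal/epithermal/fast neutron flux,
    Bateman-type reaction yield with product depression, specific
    radioactivity (SA) in atom percent and Bq/g with maximum-SA irradiation
    time solving, two-step (n,gamma) + beta-decay chain production with
    stable-carrier in-growth during and after irradiation, and isotopic
    dilution of mixed radioactive sources.  Effective cross-sections follow
    the Hogdahl convention for 1/v nuclides and a Westcott k-factor for
    non-1/v nuclides.  Ships nuclear-data fixtures and pre-wired scenarios
    for Lu-177 production by the direct Lu-176(n,gamma) route and the
    indirect Yb-176(n,gamma)Yb-177 -> beta -> Lu-177 route, plus an
    independent linear-ODE oracle (matrix exponential) used to validate
    every closed form.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
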