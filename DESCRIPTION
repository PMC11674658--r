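Package: cvchain
Title: Lumped-Parameter Model of the Cerebral Vascular Chain and CSF
    Hydrodynamics in Normal Pressure Hydrocephalus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state lumped-parameter model of the cerebral vascular
    chain (artery, capillary bed, cortical veins, venous outflow cuff) coupled
    to cerebrospinal fluid (CSF) hydrodynamics in normal pressure
    hydrocephalus (NPH). Solves the nonlinear series-resistance network under
    passive vessel response laws (capillary compliance, a quadratic venous
    transmural-pressure/volume relation, and a collapsible Starling-resistor
    outflow cuff) for a catalogue of blood-flow and intracranial-pressure
    manipulation scenarios, and provides Davson-equation arithmetic for CSF
    outflow resistance, the Starling capillary flux, a grey/white regional
    blood-flow partition, and the correction showing that constant-rate
    infusion studies overestimate CSF outflow resistance when the CSF
    formation rate rises during the test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
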