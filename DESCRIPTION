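Package: afosim
Title: Musculoskeletal Simulation of Ankle-Foot Orthoses with Viscoelastic Soft-Tissue Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sagittal-plane multibody simulation of a human leg coupled to an
    ankle-foot orthosis (AFO) through six degree-of-freedom viscoelastic
    spring-damper (bushing) interface elements that represent the compliance
    of biological soft tissue between device shells and body segments.
    Includes a tracking controller in the style of computed muscle control
    (PD feedback plus effort-optimal activation of lumped muscle groups and
    reserve actuators), a synthetic gait generator covering three walking
    speeds and four plantarflexor-weakening patient variants with paralyzed
    dorsiflexors, assistance-as-needed style support-torque profiles, and an
    experiment driver that sweeps weakening level, gait speed and device-axis
    misalignment to quantify device-to-segment relative movement and
    plantarflexor activation deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
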