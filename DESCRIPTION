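Package: ucmreach
Title: Uncontrolled Manifold Analysis of Tool-Extended Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward kinematics and Jacobian of a nine-degree-of-freedom
    arm-plus-rod kinematic chain, uncontrolled manifold (UCM) decomposition
    of joint-angle variability into goal-equivalent and non-goal-equivalent
    components, an endpoint-kinematics battery for point-to-point reaching
    (movement bounds, peak velocity, phase durations, path curvature,
    accuracy errors, time normalization), and a synthetic trial generator
    that emulates an eight-condition rod-pointing design with controllable
    null-space and orthogonal-space joint variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
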