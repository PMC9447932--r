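Package: serialdep
Title: Serial Dependence Analysis with Adaptation-Aware Population Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying serial dependence in orientation perception and
    its relation to neuronal adaptation. Implements maximum-likelihood
    psychometric fitting of binary clockwise/counterclockwise discrimination
    responses with a fixed guess rate, derivative-of-Gaussian (DoG) bias
    estimation, an encoder-decoder population model with von Mises tuning and
    gain adaptation read out by unaware, aware, overaware and Bayesian
    decoders, inverted encoding model (IEM) decoding of orientation from
    voxel patterns with circular error statistics, FIR deconvolution and
    double-gamma parameterization of hemodynamic responses with trial-wise
    response estimation, two-stage model fitting (encoding by residual sum of
    squares, readout by response likelihood) with cross-validation and model
    comparison, and seeded generators for synthetic trial sequences, observers
    and orientation-tuned voxel data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
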