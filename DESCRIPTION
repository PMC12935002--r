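Package: redoxim
Title: Ratiometric roGFP Redox Imaging and Population Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies subcellular redox state from dual-excitation roGFP2
    fluorescence microscopy. Provides a synthetic multichannel timelapse
    generator with per-object ground truth for rod-shaped cyanobacteria
    carrying cytosolic, carboxysomal, or procarboxysomal Grx1-roGFP2 sensors;
    threshold-plus-watershed cell segmentation with rule-based curation;
    puncta detection with a minimum-area filter; wild-type background
    subtraction and the R395/470 excitation ratio with clip-at-zero handling;
    population time series with standard errors, burn-in exclusion,
    Gaussian-mixture bimodality detection, hysteresis assessment, and
    two-sample comparisons; plus bulk spectrofluorometer workflows
    (chlorophyll quantification, excitation-spectrum ratios, redox-agent
    response panels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    mclust,
    igraph,
    tiff,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
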