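Package: pulmolobe
Title: Automated Lung Lobe Segmentation and Air-Trapping Quantification for
    Paired Inspiratory-Expiratory Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automatic segmentation of the six lung lobes (right upper,
    middle and lower lobe, left upper lobe, lingula, left lower lobe) on
    volumetric chest CT in Hounsfield units, following the classical
    airway-first pipeline: adaptive region growing of the airway tree,
    topology-preserving 3-D thinning and conversion of the skeleton to a
    rooted acyclic graph, rule-based lobar labeling of the bronchi, lung and
    vessel segmentation with iterative lobar assignment of vessel objects,
    Hessian-eigenvalue fissure enhancement, and a final marker-based 3-D
    watershed. Includes a paired inspiratory/expiratory thorax phantom
    generator with exact ground truth, segmentation agreement statistics
    (Dice, Jaccard, average surface distance, Bland-Altman limits of
    agreement, Pearson correlation), and lobe-based air-trapping
    quantification via the expiratory-to-inspiratory ratio of mean lung
    attenuation (E/I MLA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
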