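Package: hotspotOverlap
Title: Overlap of Baseline FDG-PET Hotspot Sub-Volumes with Local Recurrence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the spatial overlap between high-uptake
    sub-volumes delineated on a baseline FDG-PET scan and the metabolic
    volume of a subsequent local recurrence. Sub-volumes are segmented by
    relative SUVmax thresholds, scan pairs are co-registered on CT by a
    rigid and by a free-form deformable method, and agreement is measured
    with five volume-overlap indices (Dice, Jaccard, overlap fraction and
    the two directed common-volume fractions) across a threshold grid,
    together with metabolic tumor volume and total lesion glycolysis.
    Includes a synthetic PET/CT phantom generator with known ground-truth
    transforms and lesion masks, subgroup statistics comparing registration
    methods and patient-positioning regimes, and an end-to-end study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, RNifti, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: ImageRegistration, Segmentation, Software
RoxygenNote: 7.3.3
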