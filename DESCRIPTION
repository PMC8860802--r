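Package: blebpoint
Title: Multipoint Hemodynamic Analysis of Aneurysm Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of time-resolved pressure and wall shear stress
    (WSS) fields on triangulated intracranial-aneurysm surfaces using the
    multipoint method: even Poisson-disk point distribution at a fixed
    spacing, inlet-normalized pressure and WSS, time-averaged WSS and
    oscillatory shear index, detection of divergent-WSS-vector centers
    (sources of the tangential WSS field), and exact nonparametric
    comparison of bleb-formation versus bleb-free surface regions
    (Mann-Whitney U and Fisher exact tests). Includes a synthetic
    dome-on-tube generator with planted ground truth so the whole pipeline
    is testable without CFD software, plus readers and writers for ASCII
    STL/PLY/VTK surface meshes and plain-text field series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
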