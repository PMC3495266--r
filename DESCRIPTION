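Package: hippomorph
Title: Longitudinal Surface Morphometry of Corresponded Subcortical Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vertex-wise morphometry of corresponded triangulated
    surface meshes of subcortical structures (typified by the hippocampus)
    in longitudinal multi-group designs. Provides mesh I/O in legacy VTK and
    PLY formats, enclosed-volume and normal computation, a synthetic cohort
    generator emulating a three-group five-visit design with dropout,
    baseline volume and shape analyses (repeated-measures ANOVA, ANCOVA,
    PCA of corresponded surfaces with Wilks MANOVA), and longitudinal
    per-vertex slope analyses: slope maps, slope cumulative distributions,
    percent-negative and control-referenced large-magnitude slope
    statistics, and Mann-Whitney vertex-wise comparisons with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
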