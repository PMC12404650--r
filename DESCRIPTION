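Package: cuttleoptics
Title: Underwater Color Attenuation, Gamut, and Survey Statistics for
    Cephalopod Field Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative pieces of an underwater visual-ecology
    field study: fitting a per-channel Beer-Lambert model of downwelling color
    attenuation from a depth series of color-card photographs; simulating the
    ambient-light appearance of flash images at a stated depth; building
    per-depth CIELAB hue-chroma gamut polygons; aggregating searcher effort
    from 10-s dive logs and testing stratified encounter rates with an exact
    Poisson rate test; and calibrating millimeter-per-pixel scale from paired
    laser dots a fixed distance apart. A synthetic-data module renders color
    cards under known water optics, simulates stratified dive logs with
    Poisson encounters, and draws laser-dot scenes so the whole pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    jsonlite,
    png,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
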