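Package: elemaps
Title: Elemental Distribution Maps from LA-ICP-MS Line Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts folders of laser-ablation inductively-coupled-plasma
    mass-spectrometry (LA-ICP-MS) line-scan files into per-isotope elemental
    distribution maps with physically correct coordinates. Maps are normalized
    by an internal-standard isotope, optionally upsampled by bilinear
    interpolation, and exported as colour-mapped 2D/3D PNG images, CSV
    matrices (Excel, LibreOffice or custom dialects), and reloadable session
    archives. Includes a synthetic phantom generator that writes complete
    datasets (line files, acquisition parameters, stage positions) for
    testing and demonstration, and a command-line interface for scripted
    analysis runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    png,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    utils,
    stats,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
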