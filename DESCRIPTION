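Package: pkimapper
Title: Species-Targeted Spectral Index Mapping of Invasive Pedicularis kansuensis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the invasive hemiparasite Pedicularis kansuensis
    from multiband surface-reflectance imagery. Implements the P. kansuensis
    Index (PKI), a ratio of red-edge plus blue reflectance to scaled green
    reflectance, refined by grayscale morphological opening with a flat square
    structuring element; fixed-rule and boxplot-whisker threshold segmentation;
    seven benchmark vegetation and pigment indices (RI, NDVI, NDRE, GNDVI,
    CIRE, CIG, ARI); class-separability (M-statistic) and accuracy validation
    with bootstrap confidence intervals; multi-year invasion dynamics (area
    trends, density grids and marginal profiles, interannual change,
    persistence and recurrence typology); band averaging of in situ
    hyperspectral curves; and a synthetic multispectral scene simulator for
    end-to-end testing without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
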