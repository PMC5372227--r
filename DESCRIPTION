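Package: tagstitch
Title: Gapped Protein Scaffold Assembly from Top-Down Sequence Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de novo assembly of long, gapped protein sequence
    scaffolds from top-down tandem mass spectrometry data. Reads deconvoluted
    neutral-mass peak lists (msalign dialect), derives accurate k-tags from
    per-spectrum graphs of residue-mass peak differences, computes the tag
    convolution between candidate sequence fragments, estimates the
    monoisotopic mass of the gap separating two fragments of the same protein
    through scaled binning with 1 Da deconvolution-error-aware scoring and a
    coverage-based support check, and iteratively joins fragments into gapped
    paths, trying both orientations of either fragment and embedding short
    fragments into large gaps. Includes a synthetic-data generator producing
    spectra and fragment strings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
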