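Package: gazemux
Title: Bundling Gaze Trajectories, Annotations and EEG Sonification with
    Video in Matroska Containers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exchanging eye-tracking metadata together with the
    stimulus video in a single multimedia container. Gaze recordings in
    delimited text are parsed with a configurable column layout, classified
    into fixations and saccades (dispersion threshold), encoded losslessly
    as Universal Subtitle Format (USF) documents with geometric shape
    extensions, and converted lossily to Advanced Sub Station Alpha (ASS)
    subtitle tracks with vector drawing commands that ordinary media
    players render out of the box. Multiple subject tracks can be merged
    into one colour-coded track for visual comparison. A reference software
    rasterizer (Bresenham lines and circles, scan-line polygon fill)
    reproduces the overlay drawing for testing and PNG export. An EEG
    alpha-band power envelope can be sonified by frequency or amplitude
    modulation of a 220 Hz carrier and written as WAV. Subtitle tracks,
    audio tracks, the stimulus video and raw-data attachments are muxed
    into (and extracted from) Matroska (MKV) files via a built-in EBML
    backend. Seeded generators provide synthetic gaze, annotation, EEG and
    video fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    signal,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
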