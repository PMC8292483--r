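Package: locohunt
Title: Quantification of Appetitive Locomotion and Its Neural Correlates in Predatory Hunting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify predatory-hunting behavior and its neural
    correlates in rodents. Segments approach episodes from predator-prey
    tracking using azimuth and distance criteria, computes hunting metrics
    (time to capture, attack latency and frequency, approach speed and
    frequency), identifies antidromically activated units and their
    locomotion speed tuning, aligns spike trains and fiber-photometry
    dF/F traces to behavioral events with 15%-of-peak onset estimation,
    quantifies runway gait (stride length, step frequency) and
    looming-evoked escape, and normalizes synaptic puncta density in
    micrographs. Includes seeded synthetic-data generators with recorded
    ground truth for every modality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
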