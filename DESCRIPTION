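Package: sequelkit
Title: Quality Control, Subsampling and Filtering for PacBio Sequel Raw Reads
Version: 1.0.0
Authors@R:
    person("sequelkit", "developers", email = "sequelkit@example.org",
           role = c("aut", "cre"))
Description: Tools for working with raw PacBio Sequel sequence data, one
    subreads file and optionally one scraps file per SMRTcell. A quality
    control tool reconstructs continuous long reads (CLRs) from subread and
    scrap coordinates, organises reads into up to four read groups (subreads,
    longest subreads, CLRs, subedCLRs), and reports per-cell length
    statistics (N50, L50, totals, mean and median) together with the
    polymerase-to-subread ratio (PSR) and the ZMW occupancy ratio (ZOR),
    plus a configurable suite of publication-quality PDF plots. A read
    subsampling tool extracts the longest subread per CLR and/or randomly
    selected CLRs; a read filtering tool applies minimum CLR length,
    complete-pass, and normal-adapter criteria. A deterministic simulator
    generates paired subreads/scraps SMRTcell files with known per-ZMW truth
    for testing.
License: GPL-3
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
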