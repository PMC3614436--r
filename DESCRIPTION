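Package: spoolflow
Title: Rule-Based File Conversion Orchestration for Instrument Spool
    Directories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A small rule-based daemon for core facilities that must keep
    converting instrument raw data (mass-spectrometry and similar) into open
    formats without user interaction.  A single XML configuration file
    declares converter programs and packet-filter-style pass rules over file
    path metadata (project, scientific area, instrument, user, acquisition
    date, regular expressions).  Each iteration crawls a shared spool
    directory, matches candidates against the rules (block by default),
    plans idempotent jobs (skipping existing outputs, previously failed
    inputs, and converters bound to other hosts) and executes them on a
    bounded pool of workers with a central tab-separated log.  Includes a
    synthetic spool-tree generator and mock converters so the whole system
    is testable without instrument data, plus a command line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
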