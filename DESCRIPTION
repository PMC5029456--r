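Package: estromir
Title: Integrative Temporal Analysis of the Estrogen Transcriptomic Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of matched mRNA and miRNA count
    time series following estrogen stimulation. Detects estrogen-responsive
    genes with a negative-binomial Wald test against time zero and
    median-of-ratios normalization, identifies responsive miRNAs from
    reads-per-million-mapped profiles, clusters gene trajectories into
    transient, induced and repressed classes using piecewise cubic Hermite
    interpolation and Daubechies-3 wavelet features, extracts
    interval-discriminating gene sets with the characteristic-direction
    method, and ranks candidate master-regulator miRNA families by
    Monte-Carlo seed-site enrichment over 3'-UTRs. Includes a ground-truthed
    synthetic-data generator emulating a 10-timepoint, 3-replicate design so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
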