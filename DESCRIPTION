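Package: popsweep
Title: Selective-Sweep Scans, 2D-SFS Intra-Allelic Variability Tests and
    Dual-Structure Admixture Simulation
Version: 0.1.0
Authors@R:
    person("popsweep", "developers", email = "popsweep@example.org",
           role = c("aut", "cre"))
Description: Haplotype- and frequency-based population-genetic statistics
    (Hudson's FST, nucleotide diversity, Tajima's D, normalized Fay and Wu's
    H, EHH, nSL, H12, PBS, D'/r2 linkage disequilibrium and LD-block
    detection), a two-dimensional site-frequency-spectrum framework for
    detecting incomplete selective sweeps from intra-allelic variability
    with coalescent null distributions and pi-based molecular dating, a
    forward Wright-Fisher simulator of a dual-structure admixture demography
    (an isolated indigenous lineage admixing with a continental lineage)
    with selection on one lineage, ancient-DNA site-filtering policies with
    consensus haploidization, and seed-deterministic synthetic-data
    generators (coalescent panels, sweep fixtures, two-population panels,
    VCF serialization) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
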