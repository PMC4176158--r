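Package: gcassembly
Title: Combinatorial Design of Modular Shuttle Plasmids with GC-Rich
    Adaptor Overlaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale design engine for combinatorial construction of
    cyanobacterial shuttle and suicide plasmids from modular devices.
    Devices (replicons, antibiotic markers, functional cassettes) carried
    on donor plasmids are flanked by 30-nt GC-adaptor sequences; blunt
    release with EcoRV or ZraI exposes 21-nt G/C-rich terminal overlaps
    that direct isothermal (Gibson-style) assembly into a unique circular
    plasmid. The package catalogs devices and parts, validates designs
    against the vector grammars, simulates restriction release and
    overlap-guided assembly (including the one-base G/T half-site mismatch
    between EcoRV- and ZraI-released ends), handles ccdB/SwaI cloning
    cassette replacement and knockout-vector planning with adaptor-tailed
    primers, annotates assembled plasmids from a parts database, exports
    GenBank records, and emits bench digestion/assembly protocols. A
    seeded fixture generator fabricates complete device kits so the whole
    system is testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
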