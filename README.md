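# gcassembly

Desk-scale design engine for combinatorial construction of cyanobacterial
shuttle and suicide plasmids from modular devices, for synthetic
biologists building strain-engineering vectors and for anyone who wants
to validate such designs before touching a pipette.

## The scheme

Devices -- replicons, E. coli origins, antibiotic markers, functional
cassettes -- live on donor plasmids between 30-nt **GC-adaptor** flanks:

```
release site (EcoRV GAT^ATC or ZraI GAC^GTC) + 15-bp G/C core + GAT + secondary site
```

Blunt release leaves each fragment end carrying a 21-nt overlap,
`half-site + core + GAT` (half-site `ATC` for EcoRV, `GTC` for ZraI).
Four core classes (G5C5, C3G3, GC, C2G), each used in two orientations,
are assigned to device categories so that only grammatically adjacent
devices share identical terminal 21-mers; the overlaps therefore dictate
the order and orientation of the circle formed by isothermal
(Gibson-style) assembly. All cores are 15/15 G+C, so every overlap melts
at 76-78 °C by the Wallace rule (2 °C per A/T, 4 °C per G/C) -- above
the 50 °C reaction temperature. A joint between a ZraI-released and an
EcoRV-released end carries exactly one half-site mismatch (the G/T
heteroduplex), which the assembler records and normalizes to the EcoRV
dialect in the output sequence.

The package catalogs devices and parts (JSON manifest + GenBank),
validates designs against the vector grammars (4-device strain-specific,
3-device broad-host-range and neutral-site, 2-device + 2-homology-arm
knockout), simulates release and overlap-guided assembly into a unique
circle, handles ccdB/SwaI cloning-cassette replacement and adaptor-tailed
primer design, annotates products from a parts database, exports GenBank,
and prints bench digestion/assembly protocols. A seeded fixture generator
fabricates complete device kits, so nothing needs to be downloaded.

## Worked example

```r
library(gcassembly)

kit <- generate_fixture_kit(seed = 1)
kit
#> <catalog> 4 device(s), 4 donor plasmid(s), 5 part(s)
#>   pDU1_syn (cyano_replicon, 100 nt, ZraI)
#>   oriEc_syn (ecoli_origin_paired, 100 nt, EcoRV)
#>   aadA_cass_syn (antibiotic_marker, 100 nt, EcoRV)
#>   ccdB_cass_syn (cloning_cassette, 100 nt, EcoRV)

plan <- plan_vector("self_replicating_strain_specific",
                    names(kit$devices), catalog = kit)
plasmid <- assemble(plan, kit, id = "pFix1")
plasmid
#> <assembled plasmid> pFix1, 532 bp circular, 4 junction(s), 4 feature(s)
#>        upstream    downstream class overlap mismatch_count wallace_tm_C
#> 1      pDU1_syn     oriEc_syn  C3G3      21              1           76
#> 2     oriEc_syn aadA_cass_syn    GC      21              0           76
#> 3 aadA_cass_syn ccdB_cass_syn   C2G      21              0           76
#> 4 ccdB_cass_syn      pDU1_syn  G5C5      21              1           76
```

Each of the four devices contributes a 154-nt fragment (100-nt payload +
two 27-nt adaptor remnants); the circle is 4×154 − 4×21 = 532 bp. The
replicon fixture is ZraI-released (it carries an internal EcoRV site),
so its two joints each show the single half-site mismatch; the
EcoRV-EcoRV joints match 21/21. Every junction melts at ≥ 76 °C.

```r
generate_protocol(plan, donors = kit)
#> Assembly protocol (self_replicating_strain_specific vector)
#>
#> 1. Restriction release
#>    Pool 1 (EcoRV): pDonor_oriEc_syn, pDonor_aadA_cass_syn, pDonor_ccdB_cass_syn
#>    Pool 2 (ZraI): pDonor_pDU1_syn
#>    Digest each pool with 5 U of enzyme per ug of plasmid DNA for 3 to 5 h at 37 C,
#>    in a final volume at least 50x the volume of enzyme added.
#>    [DNA mass and reaction volume are laboratory-adjustable.]
#>
#> 2. Clean-up: purify and concentrate the digests with a DNA clean-up/concentration kit.
#>
#> 3. Isothermal assembly: combine the released fragments and incubate the assembly reaction at 50 C.
```

`write_genbank(plasmid, "pFix1.gb")` exports the annotated circle. The
same pipeline is scriptable from a shell via `inst/cli/gcassembly.R`
(`fixtures generate`, `catalog`, `validate`, `plan`, `assemble`,
`annotate`, `protocol`, `primers`).

See `vignette("gc-adaptor-assembly")` for the model, parameter defaults
and design choices.

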