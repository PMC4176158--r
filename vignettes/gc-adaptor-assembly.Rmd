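---
title: "GC-adaptor assembly: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC-adaptor assembly: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcassembly)
```

## The assembly scheme

gcassembly simulates a combinatorial plasmid-construction scheme for
cyanobacterial shuttle and suicide vectors. The unit of reuse is a
*device*: a functional block (replicon, E. coli origin, antibiotic
marker, expression/reporter/cloning cassette) kept on an E. coli donor
plasmid between two 30-nt *GC-adaptor flanks*. Each flank decomposes as

```
release site (6 nt) + G/C core (15 nt) + GAT half-site (3 nt) + secondary site (6 nt)
```

The release site is a blunt cutter, EcoRV (`GAT^ATC`) or ZraI
(`GAC^GTC`). Cutting both flanks drops the device out as a blunt linear
fragment whose two termini each carry a 21-nt sequence: the residual
half-site (`ATC` for EcoRV, `GTC` for ZraI), the 15-bp core, and `GAT`.
Four core classes exist (G5C5, C3G3, GC, C2G), all 15/15 G+C, each with
two distinguishable orientations (the core and its reverse complement
are different strings). Because a device category is assigned a fixed
ordered pair of flank classes, the terminal 21-mers of released
fragments overlap identically only between categories that are adjacent
in the vector grammar -- the overlaps dictate both the order and the
orientation of the circle that isothermal (Gibson-style) assembly
produces. The all-G/C cores push every overlap's Wallace melting
temperature to 76--78 C, comfortably above the 50 C at which the
isothermal reaction runs.

A device's right flank is stored as the published string *on the bottom
strand*: on the device's top strand it appears reverse-complemented,
which places its release site distal to the payload and makes the
upstream fragment's terminal 21-mer identical to the downstream
fragment's. This storage convention is the only arrangement that
reproduces identical facing overlaps and is applied consistently by the
catalog, the GenBank importer and the primer designer.

### The EcoRV/ZraI half-site mismatch

EcoRV is the default release enzyme; ZraI substitutes when a device's
own sequence contains an EcoRV site (`choose_enzyme()`; a payload
containing both sites is rejected). The two enzymes leave half-sites
differing in one base, so a joint between a ZraI-released end and an
EcoRV-released end carries exactly one mismatch, at overlap position 1
or 21 and always between bases {G,A} or {C,T} on the top strand -- the
G/T (equivalently A/C) heteroduplex. A ZraI-released device has ZraI
ends on *both* sides, so in a mixed assembly both of its joints carry
one mismatch each. When the assembled sequence is written, each overlap
appears once, with mismatch positions normalized to the EcoRV-dialect
base (`ATC`/`GAT`); assembling the same devices under different release
enzymes therefore yields byte-identical output, and the heteroduplex is
retained in the junction report rather than in the sequence. The
physical repair outcome of the heteroduplex is not modeled; only the
count and position of the mismatch are asserted.

## Vector grammars

Four templates are supported, each a fixed circular order of device
categories whose adaptor classes chain head-to-tail:

| template | slots | devices | custom PCR fragments |
|---|---|---|---|
| self_replicating_strain_specific | cyano replicon, paired E. coli origin, marker, functional | 4 | 0 |
| broad_host_range | BHR replicon, marker, functional | 3 | 0 |
| neutral_site_integration | neutral site, marker, functional | 3 | 0 |
| knockout | knockout E. coli origin, upstream arm, marker, downstream arm | 2 | 2 |

Users choose devices; the grammar orders them. One functional slot is
allowed per plasmid; anything that fits no slot, or a second device for
an occupied slot, is rejected at planning time, as is any cyclically
adjacent face pair that fails `face_pairing()`. Knockout homology arms
are custom PCR fragments: their tails are the full 30-nt flanks
(classes C3G3|GC upstream and C2G|G5C5 downstream, inferred from the
class-assignment rules since the published table fixes only the
topology), and in silico the tailed amplicon is digested with its
release enzyme before assembly so that its ends are ordinary 21-mers.

Published flank strings are bundled verbatim (uppercased; case in the
printed table is typographic, not semantic). Categories for which the
table prints a single flank take the missing face from the class
assignment -- always the G5C5-XbaI / XbaI-G5C5 pair. Because a device's
two faces must share one release enzyme while the printed flanks carry
fixed sites, the 6-nt release-site prefix of a face follows the
device's chosen enzyme; the rest of the flank is invariant.

## The cloning cassette

The replaceable cassette carries a ccdB counterselection gene bracketed
by two SwaI sites (`ATTT^AAAT`), with two free-form 25-nt adaptors
outside them:

```
TAGTCGGCCAATAACCCAGGGATTT   and   CTCCTGCCGGGGAGCTCCTTCATTT
```

Both end in `ATTT`, the first half of the SwaI site, so the sites
regenerate on insertion. Opening the vector with SwaI drops the toxic
fragment; an insert amplified with these tails joins the backbone
through two exact 25-nt overlaps (custom overlaps never tolerate
mismatches). Both tails meet the 50 C Wallace bound (74 and 80 C). The
hairpin screen at its default thresholds (stem >= 4, loop >= 3) passes
the first tail and reports one weak 4-bp stem (CTCC/GGAG, 6-nt loop) in
the second; at stem >= 5 both pass. The screen is a conservative
design-time filter -- two reverse-complementary substrings separated by
a minimal loop -- not a thermodynamic folding prediction, and reporting
marginal stems is intended behavior for a tool meant to flag candidate
adaptors for human review.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `melting_params()$method` | `wallace` | -- | 2 C per A/T + 4 C per G/C; deterministic integer arithmetic. A nearest-neighbor option (SantaLucia 1998 unified parameters, 50 mM monovalent, 250 pM strand) is provided, but the >= 50 C bound on the 15/15 G+C cores holds under any standard formula, so the simple rule is the reference. |
| `melting_params()$threshold_C` | 50 | C | the isothermal assembly reaction temperature. |
| `find_junctions()` `min_overlap` | 15 | nt | shortest overlap considered; adaptor overlaps are 21, cassette overlaps 25. |
| `find_junctions()` `max_mismatch` | 1 | -- | admits the single EcoRV/ZraI half-site heteroduplex; custom overlaps require 0. |
| `hairpin_screen()` `min_stem`, `min_loop` | 4, 3 | nt | conservative screen thresholds; the goal (no single-strand secondary structure) is published, the screen itself is a package choice. |
| `plan_knockout()` `min_homology` | 100 | nt | floor for recombination arm length; configurable. |
| `save_catalog()` `inline_max` | 200 | nt | longer sequences go to sibling GenBank files to keep the JSON manifest diff-able. |

## Coordinates and numerical conventions

All coordinates are 1-based inclusive, the R/Bioconductor convention,
including `scan_sites()` output; GenBank export needs no conversion. A
feature or junction spanning the circular origin is represented with
`end > length` and written with the `join(a..N,1..b)` convention.
Assembled circles are reported as the lexicographically minimal
rotation of the strand on which the first-listed fragment lies forward,
which makes assembly invariant to the order fragments are supplied and
deterministic across runs; fragments supplied in flipped orientation
are joined through their reverse complement. Overlapping and nested
recognition sites are each reported and each cut. GenBank files carry a
fixed LOCUS date so identical inputs give byte-identical output.

`assemble_circle()` succeeds only when the junction graph admits
exactly one circular order over all fragments, established by
exhaustive anchored search (fragment counts here are 3--5, so
enumeration is exact and cheap). Zero tours is an "open assembly" error
naming the unpaired ends -- note that a duplicated antibiotic marker
produces this verdict, not ambiguity, because a marker's right face
(C2G) can never pair with a second marker's left face (GC). Two or more
tours (e.g. interchangeable duplicates in alternating slots) is an
"ambiguous assembly" error listing the alternatives.

## What the synthetic fixtures emulate

The fixture generator stands in for the published donor-plasmid
library, which is not required to build or test the package. It draws
payloads base-by-base at a stated G+C fraction (default 0.5, 100 nt)
from R's Mersenne-Twister stream under an explicit integer seed, and
resamples until the payload is free of EcoRV, ZraI and SwaI sites on
both strands (bounded retries); donors wrap the flanked device in a
~2.7-kb synthetic backbone carrying a synthetic marker part. A
cyanobacterial-replicon fixture plants one internal EcoRV site to force
ZraI release, reproducing the mixed-enzyme situation the scheme was
designed around. The standard kit is four 100-nt-payload devices, which
assemble into a 532-bp circle (4 x 154 - 4 x 21) -- large enough to
exercise every junction class and small enough that the whole suite
runs in seconds.

Synthetic payloads are uniform random DNA: they have no promoters,
repeats, GC skew or biological structure, and the ccdB stand-in is a
random 42-mer, not the real gene. Passing tests therefore demonstrate
the correctness of the combinatorial sequence algebra (release,
overlap matching, uniqueness, annotation, round-trips), not that any
particular natural replicon or marker behaves as annotated, and say
nothing about wet-lab assembly efficiency, antibiotic performance or
expression levels, which are outside the package's scope.

## Known limitations

* Blunt cutters only; sticky ends, methylation sensitivity and star
  activity are not modeled.
* No thermodynamic secondary-structure prediction; the hairpin screen
  is combinatorial.
* No modeling of exonuclease kinetics, misassembly probability, or
  transformation/conjugation efficiency; PCR is simulated as tail
  concatenation.
* Plasmid maps are textual (feature tables), not graphical.
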