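# Shared fixtures, built once per test run. Seeds are part of the study
# conditions and are fixed.

fixture_kit <- local({
  kit <- NULL
  function() {
    if (is.null(kit)) kit <<- generate_fixture_kit(1)
    kit
  }
})

fixture_plan <- function(kit = fixture_kit()) {
  plan_vector("self_replicating_strain_specific", names(kit$devices),
              catalog = kit)
}

fixture_assembly <- local({
  pl <- NULL
  function() {
    if (is.null(pl)) {
      kit <- fixture_kit()
      pl <<- assemble(fixture_plan(kit), kit, id = "pFix1")
    }
    pl
  }
})

# a clean (no internal site) 4-device set releasable by either enzyme,
# for the EcoRV-vs-ZraI normalization check
clean_device_set <- local({
  made <- NULL
  function() {
    if (is.null(made)) {
      cats <- c("cyano_replicon", "ecoli_origin_paired",
                "antibiotic_marker", "expression_cassette")
      gens <- lapply(seq_along(cats), function(i)
        generate_device(1000 + i, paste0("dev", i), cats[i], 100))
      made <<- gens
    }
    made
  }
})

# rebuild one device of a generated set with a forced release enzyme,
# wrapping it in a fresh deterministic backbone
reenzyme_device <- function(gen, enzyme, seed) {
  d <- gen$device
  d2 <- device_record(d$id, d$category, d$payload$bases, parts = d$parts,
                      enzyme = enzyme)
  backbone <- gcassembly:::with_rng(seed, function()
    gcassembly:::random_clean(2700, 0.5))
  list(device = d2, donor = donor_plasmid(d2, backbone))
}

random_clean_seq <- function(seed, n, gc = 0.5) {
  gcassembly:::with_rng(seed, function() gcassembly:::random_clean(n, gc))
}

# does `pattern` occur on the circle (origin-spanning included)?
on_circle <- function(pattern, circ_seq) {
  grepl(pattern, paste0(circ_seq, circ_seq), fixed = TRUE)
}

# hand-built fragment whose terminal 21-mers come straight from the
# adaptor faces (EcoRV dialect), used to construct degenerate graphs
synthetic_fragment <- function(id, left_label, right_label, seed,
                               mid_length = 100) {
  lf <- adaptor_face(left_label, "EcoRV")
  rf <- adaptor_face(right_label, "EcoRV")
  seqc <- paste0(junction_21mer(lf, "EcoRV"),
                 random_clean_seq(seed, mid_length),
                 oracle_rc(junction_21mer(rf, "EcoRV")))
  gcassembly:::new_fragment(id, seqc,
                            gcassembly:::adaptor_end(lf, "EcoRV"),
                            gcassembly:::adaptor_end(rf, "EcoRV"))
}

# four fragments in two interchangeable category pairs: two distinct
# circular orders exist (swap the two B fragments)
ambiguous_fragment_set <- function() {
  list(synthetic_fragment("A1", "C3G3-MfeI", "NheI-GC", 301),
       synthetic_fragment("B1", "GC-NheI", "SacI-C3G3", 302),
       synthetic_fragment("A2", "C3G3-MfeI", "NheI-GC", 303),
       synthetic_fragment("B2", "GC-NheI", "SacI-C3G3", 304))
}
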