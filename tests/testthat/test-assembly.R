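test_that("vector templates carry the published module counts", {
  tpl <- vector_templates()
  expect_identical(tpl$self_replicating_strain_specific$n_devices, 4L)
  expect_identical(tpl$broad_host_range$n_devices, 3L)
  expect_identical(tpl$neutral_site_integration$n_devices, 3L)
  expect_identical(tpl$knockout$n_devices, 2L)
  expect_identical(tpl$knockout$n_custom, 2L)
  expect_length(tpl$knockout$slots, 4L)
})

test_that("planning fills slots by category and rejects bad selections", {
  kit <- fixture_kit()
  plan <- fixture_plan(kit)
  expect_length(plan$slots, 4L)
  expect_identical(vapply(plan$slots, `[[`, character(1), "slot"),
                   c("cyano_replicon", "ecoli_origin_paired",
                     "antibiotic_marker", "functional"))
  expect_error(plan_vector("self_replicating_strain_specific",
                           names(kit$devices)[-1], catalog = kit),
               "missing device for slot cyano_replicon")
  expect_error(plan_vector("broad_host_range", names(kit$devices),
                           catalog = kit),
               "missing device for slot bhr_replicon")
  expect_error(plan_vector("nonsense", names(kit$devices), catalog = kit),
               "unknown vector type")
  expect_error(plan_vector("self_replicating_strain_specific",
                           c(names(kit$devices), "ghost"), catalog = kit),
               "not in catalog")
})

test_that("released fragments carry adaptor arithmetic and tolerate stray backbone sites", {
  kit <- fixture_kit()
  frags <- release_fragments(fixture_plan(kit), kit)
  expect_length(frags, 4L)
  expect_identical(vapply(frags, function(f) nchar(f$seq), integer(1)),
                   rep(154L, 4L))  # 100 + 2 x 27
  # stray EcoRV site in the backbone only adds a backbone piece
  d <- kit$devices[["aadA_cass_syn"]]
  stray_backbone <- paste0(random_clean_seq(31, 1000), "GATATC",
                           random_clean_seq(32, 1000))
  donor2 <- donor_plasmid(d, stray_backbone, id = "pDonor_stray")
  frags2 <- blunt_digest(donor2$sequence, "EcoRV")
  expect_length(frags2, 3L)
  plan1 <- plan_vector("self_replicating_strain_specific",
                       names(kit$devices), catalog = kit)
  donors2 <- kit$donors
  donors2[["pDonor_aadA_cass_syn"]] <- donor2
  rel <- release_fragments(plan1, donors2)
  expect_identical(nchar(rel[[3]]$seq), 154L)
  # a cut payload is an error naming the donor
  dcut <- d
  dcut$payload <- dna(paste0(strrep("A", 40), "GATATC", strrep("T", 54)))
  donor_bad <- structure(list(id = "pDonor_bad", device_id = d$id,
                              sequence = dna(paste0(
                                random_clean_seq(33, 500),
                                gcassembly:::device_insert(dcut)),
                                "circular")),
                         class = "gc_donor")
  plan_bad <- plan1
  plan_bad$slots[[3]]$device <- dcut
  donors_bad <- donors2
  donors_bad[["pDonor_aadA_cass_syn"]] <- donor_bad
  expect_error(release_fragments(plan_bad, donors_bad),
               "pDonor_bad.*does not release device")
})

test_that("junction finding matches same-class ends and flags the half-site mismatch", {
  kit <- fixture_kit()
  frags <- release_fragments(fixture_plan(kit), kit)
  graph <- find_junctions(frags)
  fwd <- Filter(function(e) !e$from_flip && !e$to_flip, graph$edges)
  expect_length(fwd, 4L)
  for (e in fwd) {
    expect_identical(e$overlap, 21L)
    expect_true(e$mismatch_count %in% c(0L, 1L))
    if (e$mismatch_count == 1L)
      expect_true(all(e$mismatch_positions %in% c(1L, 21L)))
  }
  # ZraI device joints carry the mismatch; EcoRV-EcoRV joints are exact
  by_pair <- function(up, dn) Filter(function(e)
    e$upstream == up && e$downstream == dn, fwd)[[1]]
  expect_identical(by_pair("pDU1_syn", "oriEc_syn")$mismatch_count, 1L)
  expect_identical(by_pair("ccdB_cass_syn", "pDU1_syn")$mismatch_count, 1L)
  expect_identical(by_pair("oriEc_syn", "aadA_cass_syn")$mismatch_count, 0L)
  # incompatible classes draw no edge (marker right C2G vs marker left GC)
  expect_null(gcassembly:::align_overlap(
    frags[[3]]$seq, frags[[3]]$seq, 1L, 15L))  # C2G right vs GC-NheI left
  expect_error(find_junctions(frags[1]), "at least two fragments")
})

test_that("assembly yields one 532-nt circle with four junctions", {
  pl <- fixture_assembly()
  expect_identical(nchar(pl$sequence$bases), 532L)  # 4 x 154 - 4 x 21
  expect_identical(pl$sequence$topology, "circular")
  expect_identical(nrow(pl$junctions), 4L)
  expect_true(all(pl$junctions$overlap == 21L))
  expect_true(all(pl$junctions$wallace_tm_C >= 50L))
  # exactly the two joints that touch the ZraI-released device mismatch
  expect_identical(sum(pl$junctions$mismatch_count), 2L)
  mism <- pl$junctions[pl$junctions$mismatch_count == 1L, ]
  expect_setequal(unique(c(mism$upstream, mism$downstream)),
                  c("pDU1_syn", "oriEc_syn", "ccdB_cass_syn"))
})

test_that("assembly is invariant to input order and reports open or ambiguous graphs", {
  kit <- fixture_kit()
  frags <- release_fragments(fixture_plan(kit), kit)
  ref <- assemble_circle(find_junctions(frags))
  set.seed(41)
  for (i in 1:3) {
    perm <- sample(4)
    out <- assemble_circle(find_junctions(frags[perm]))
    expect_identical(out$sequence$bases, ref$sequence$bases)
  }
  # flipping a fragment flips it back during junction search
  flipped <- frags
  flipped[[2]]$seq <- oracle_rc(flipped[[2]]$seq)
  tmp <- flipped[[2]]$left_end
  flipped[[2]]$left_end <- flipped[[2]]$right_end
  flipped[[2]]$right_end <- tmp
  out_f <- assemble_circle(find_junctions(flipped))
  expect_identical(out_f$sequence$bases, ref$sequence$bases)
  # dropping a fragment leaves an open assembly naming the unpaired classes
  err <- tryCatch(assemble_circle(find_junctions(frags[-2])),
                  error = conditionMessage)
  expect_match(err, "open assembly")
  expect_match(err, "C3G3")
  expect_match(err, "GC")
  # a duplicated marker cannot be placed: its C2G right face never pairs
  # with the second copy's GC left face, so the graph has no closed tour
  dup <- c(frags, list(frags[[3]]))
  dup[[5]]$id <- "marker_copy"
  expect_error(assemble_circle(find_junctions(dup)), "open assembly")
  # interchangeable duplicates in alternating slots are ambiguous
  amb <- ambiguous_fragment_set()
  expect_error(assemble_circle(find_junctions(amb)), "ambiguous assembly")
})

test_that("the uniqueness verdict agrees with exhaustive enumeration", {
  kit <- fixture_kit()
  frags <- release_fragments(fixture_plan(kit), kit)
  seqs <- lapply(frags, `[[`, "seq")
  expect_identical(oracle_count_circles(seqs), 1L)
  expect_identical(oracle_count_circles(seqs[-2]), 0L)
  # duplicated marker: exhaustive search also finds no circle over all 5
  expect_identical(oracle_count_circles(c(seqs, seqs[3])), 0L)
  # alternating duplicates: exhaustive search finds more than one circle
  amb <- lapply(ambiguous_fragment_set(), `[[`, "seq")
  expect_gt(oracle_count_circles(amb), 1L)
})

test_that("EcoRV-only and ZraI-mixed releases assemble to the same normalized sequence", {
  gens <- clean_device_set()
  donors_a <- lapply(gens, `[[`, "donor")
  devs_a <- lapply(gens, `[[`, "device")
  expect_true(all(vapply(devs_a, `[[`, character(1), "release_enzyme") ==
                    "EcoRV"))
  plan_a <- plan_vector("self_replicating_strain_specific", devs_a)
  out_a <- assemble(plan_a, donors_a)
  # same devices, replicon re-released with ZraI
  z <- reenzyme_device(gens[[1]], "ZraI", seed = 2001)
  devs_b <- devs_a; devs_b[[1]] <- z$device
  donors_b <- donors_a; donors_b[[1]] <- z$donor
  out_b <- assemble(plan_vector("self_replicating_strain_specific", devs_b),
                    donors_b)
  expect_identical(sum(out_b$junctions$mismatch_count), 2L)
  expect_identical(out_a$sequence$bases, out_b$sequence$bases)
  expect_identical(sum(out_a$junctions$mismatch_count), 0L)
})

test_that("the ccdB cassette is replaced through the two 25-nt overlaps", {
  kit <- fixture_kit()
  pl <- fixture_assembly()
  tails <- cassette_adaptors()
  ccdb <- kit$parts$sequence[kit$parts$id == "ccdB_syn"]
  expect_true(grepl(ccdb, pl$sequence$bases, fixed = TRUE))
  mid <- random_clean_seq(77, 200)
  insert <- paste0(tails[["left"]], mid, oracle_rc(tails[["right"]]))
  out <- insert_into_cloning_cassette(pl, insert, parts = kit$parts)
  expect_false(on_circle(ccdb, out$sequence$bases))
  expect_true(on_circle(mid, out$sequence$bases))
  expect_identical(nrow(out$junctions), 2L)
  expect_true(all(out$junctions$overlap == 25L))
  expect_true(all(out$junctions$mismatch_count == 0L))
  expect_error(insert_into_cloning_cassette(pl, mid), "tail mismatch")
  no_swai <- dna(random_clean_seq(78, 400), "circular")
  expect_error(insert_into_cloning_cassette(no_swai, insert),
               "no SwaI cloning cassette")
  # both published tails meet the assembly-temperature bound
  expect_gte(wallace_tm(tails[["left"]]), 50L)
  expect_gte(wallace_tm(tails[["right"]]), 50L)
  expect_true(hairpin_screen(tails[["left"]])$pass)
})

test_that("tailed primers reproduce the published flanks and release cleanly", {
  fwd <- "ATGGCTAGCAAACCCGGGTT"
  rev <- "TTACCCAAAGGGTTTCCCAA"
  pp <- design_tailed_primers(fwd, rev, "G5C5-XbaI", "SacI-C3G3")
  expect_identical(nchar(pp$forward), 50L)
  expect_true(startsWith(pp$forward, "GACGTCGGGGG"))
  expect_identical(pp$enzyme, "ZraI")
  target <- paste0(fwd, random_clean_seq(55, 60), oracle_rc(rev))
  amp <- simulate_amplicon(pp, target)
  frags <- blunt_digest(amp, "ZraI")
  mid <- Filter(function(f) !is.na(f$left_enzyme) && !is.na(f$right_enzyme),
                frags)[[1]]
  expect_identical(substr(mid$seq, 1, 21),
                   junction_21mer(adaptor_face("G5C5-XbaI"), "ZraI"))
  expect_error(design_tailed_primers("", rev, "G5C5-XbaI", "SacI-C3G3"),
               "non-empty")
  expect_error(simulate_amplicon(pp, "AAAA"), "do not match the target")
})

test_that("knockout plans wire two devices and two homology arms into one circle", {
  kit <- fixture_kit()
  backbone <- generate_device(42, "oriKO_syn", "ecoli_origin_knockout", 100)
  up <- random_clean_seq(7, 300)
  dn <- random_clean_seq(8, 300)
  plan <- plan_knockout(up, dn, marker = kit$devices[["aadA_cass_syn"]],
                        backbone = backbone$device)
  kinds <- vapply(plan$slots, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "device"), 2L)
  expect_identical(sum(kinds == "custom"), 2L)
  donors <- c(kit$donors, list(backbone$donor))
  out <- assemble(plan, donors, id = "pKO")
  expect_identical(nchar(out$sequence$bases),
                   154L + 154L + 2L * (300L + 54L) - 4L * 21L)
  expect_identical(nrow(out$junctions), 4L)
  expect_true(on_circle(up, out$sequence$bases))
  expect_error(plan_knockout(up, dn, marker = kit$devices[["ccdB_cass_syn"]],
                             backbone = backbone$device),
               "must be antibiotic_marker")
  expect_error(plan_knockout(substr(up, 1, 50), dn,
                             marker = kit$devices[["aadA_cass_syn"]],
                             backbone = backbone$device),
               "homology too short")
  expect_error(plan_vector("knockout",
                           list(backbone$device,
                                kit$devices[["aadA_cass_syn"]]),
                           custom = list(upstream = up)),
               "missing the custom downstream")
})
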