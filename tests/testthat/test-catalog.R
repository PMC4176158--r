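test_that("release-enzyme choice is EcoRV-first with ZraI fallback", {
  expect_identical(choose_enzyme(strrep("AAATTT", 10))$name, "EcoRV")
  expect_identical(choose_enzyme(paste0(strrep("AT", 20), "GATATC",
                                        strrep("CA", 20)))$name, "ZraI")
  expect_error(choose_enzyme("AAGATATCAAGACGTCAA"),
               "no compatible release enzyme")
  # consistency with the published flank table: GACGTC flanks imply ZraI,
  # GATATC flanks imply EcoRV
  flanks <- adaptor_flanks()
  for (i in seq_len(nrow(flanks))) {
    printed <- substr(flanks$flank[i], 1, 6)
    expect_identical(printed,
                     enzymes()[[flanks$enzyme[i]]]$recognition)
  }
})

test_that("device validation reports flank, enzyme and internal-site violations", {
  marker <- generate_device(21, "mk", "antibiotic_marker", 100)$device
  expect_true(validate_device(marker)$valid)
  # wrong flank classes for the category
  broken <- marker
  broken$left_face <- adaptor_face("G5C5-XbaI", "EcoRV")
  broken$right_face <- adaptor_face("SacI-C3G3", "EcoRV")
  rep <- validate_device(broken)
  expect_false(rep$valid)
  expect_match(paste(rep$violations, collapse = " "),
               "flank class mismatch")
  # payload carrying its own release site, with the position named
  cut <- marker
  cut$payload <- dna(paste0(strrep("A", 10), "GATATC", strrep("T", 30)))
  rep2 <- validate_device(cut)
  expect_false(rep2$valid)
  expect_match(paste(rep2$violations, collapse = " "),
               "EcoRV site\\(s\\) at position\\(s\\) 11")
  # mismatched face enzymes
  mixed <- marker
  mixed$right_face <- adaptor_face(marker$right_face$label, "ZraI")
  expect_false(validate_device(mixed)$valid)
})

test_that("donor digestion releases terminal 21-mers matching the faces", {
  kit <- fixture_kit()
  for (d in kit$devices) {
    donor <- gcassembly:::donor_for_device(kit, d$id)
    frags <- blunt_digest(donor$sequence, d$release_enzyme)
    expect_length(frags, 2L)
    dev_frag <- frags[[which(vapply(frags, function(f)
      grepl(d$payload$bases, f$seq, fixed = TRUE), logical(1)))]]
    s <- dev_frag$seq
    expect_identical(substr(s, 1, 21),
                     junction_21mer(d$left_face, d$release_enzyme))
    expect_identical(substr(s, nchar(s) - 20, nchar(s)),
                     oracle_rc(junction_21mer(d$right_face,
                                              d$release_enzyme)))
  }
})

test_that("catalog manifests round-trip byte-identically", {
  kit <- fixture_kit()
  d1 <- file.path(tempdir(), "cat_rt1")
  d2 <- file.path(tempdir(), "cat_rt2")
  dir.create(d1, showWarnings = FALSE)
  dir.create(d2, showWarnings = FALSE)
  save_catalog(kit, file.path(d1, "manifest.json"))
  k2 <- load_catalog(file.path(d1, "manifest.json"))
  expect_identical(names(k2$devices), sort(names(kit$devices)))
  expect_identical(k2$devices[["pDU1_syn"]]$payload$bases,
                   kit$devices[["pDU1_syn"]]$payload$bases)
  save_catalog(k2, file.path(d2, "manifest.json"))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)))
})

test_that("manifest loading rejects schema violations and duplicates", {
  kit <- fixture_kit()
  expect_error(catalog(devices = c(kit$devices, kit$devices["pDU1_syn"])),
               "duplicate device id")
  dir <- file.path(tempdir(), "cat_bad")
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format = "something-else", version = 1,
                            parts = list(), devices = list(),
                            donor_plasmids = list()),
                       path, auto_unbox = TRUE)
  expect_error(load_catalog(path), "schema violation")
  jsonlite::write_json(list(format = "gcassembly-catalog", version = 1,
                            parts = list(),
                            devices = list(list(id = "x", category =
                              "antibiotic_marker", release_enzyme = "EcoRV",
                              payload_file = "missing.gb")),
                            donor_plasmids = list()),
                       path, auto_unbox = TRUE)
  expect_error(load_catalog(path), "missing referenced file")
  expect_error(load_catalog(file.path(dir, "nothere.json")),
               "manifest not found")
})

test_that("devices import from GenBank records with flank detection", {
  kit <- fixture_kit()
  d <- kit$devices[["aadA_cass_syn"]]
  insert <- gcassembly:::device_insert(d)
  path <- file.path(tempdir(), "device.gb")
  ft <- data.frame(key = "misc_feature", start = 30L + d$parts$start,
                   end = 30L + d$parts$end, strand = d$parts$strand,
                   label = d$parts$part_id, stringsAsFactors = FALSE)
  write_genbank(gcassembly:::gc_record("aadA_import", dna(insert), ft), path)
  imported <- device_from_genbank(path, "antibiotic_marker")
  expect_identical(imported$payload$bases, d$payload$bases)
  expect_identical(imported$left_face$label, d$left_face$label)
  expect_identical(imported$right_face$label, d$right_face$label)
  expect_identical(imported$parts$part_id, d$parts$part_id)
  expect_identical(imported$parts$start, d$parts$start)
  # lowercase flanks parse (case-normalized)
  rec <- read_genbank(path)
  rec$sequence <- dna(tolower(insert))
  expect_identical(device_from_genbank(rec, "antibiotic_marker")$payload$bases,
                   d$payload$bases)
  # record missing its right flank fails with a parse error
  rec$sequence <- dna(substr(insert, 1, nchar(insert) - 30L))
  expect_error(device_from_genbank(rec, "antibiotic_marker"),
               "right flank does not parse")
})

test_that("parts databases import from TSV and FASTA", {
  kit <- fixture_kit()
  tsv <- file.path(tempdir(), "parts.tsv")
  write_parts_tsv(kit$parts, tsv)
  back <- read_parts_tsv(tsv)
  expect_identical(back$id, kit$parts$id)
  expect_identical(back$sequence, kit$parts$sequence)
  fa <- file.path(tempdir(), "parts.fa")
  writeLines(c(">p1|CDS|part one", "ACGTACGT", ">p2", "GGGCCC"), fa)
  parts <- read_parts_fasta(fa)
  expect_identical(parts$role, c("CDS", "other"))
  expect_identical(parts$sequence, c("ACGTACGT", "GGGCCC"))
})
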