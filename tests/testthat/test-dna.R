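test_that("reverse complement matches an independent oracle and involutes", {
  expect_identical(reverse_complement("GAT"), "ATC")
  expect_identical(reverse_complement("GACGTC"), "GACGTC")  # palindrome
  expect_identical(reverse_complement("GGGGGCCCCCGGGGG"), "CCCCCGGGGGCCCCC")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
               collapse = "")
    expect_identical(reverse_complement(s), oracle_rc(s))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  circ <- dna("ACGTAA", "circular")
  expect_identical(reverse_complement(circ)$topology, "circular")
  expect_error(dna("ACGN"), "invalid characters")
})

test_that("site scanning handles linear, circular and origin-spanning cases", {
  expect_identical(scan_sites(dna("GATATC"), "EcoRV"), 1L)
  flank <- "GACGTCGGGGGCCCCCGGGGGGATTCTAGA"
  expect_identical(scan_sites(dna(flank), "EcoRV"), integer(0))
  expect_identical(scan_sites(dna(flank), "ZraI"), 1L)
  # origin-spanning site on a circle
  expect_identical(scan_sites(dna("ATCAAAAAAGAT", "circular"), "EcoRV"), 10L)
  # property: circular scan equals rotation-based oracle on short sequences
  set.seed(12)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(12:60, 1), TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
    for (enz in c("EcoRV", "ZraI", "SwaI")) {
      rec <- enzymes()[[enz]]$recognition
      expect_identical(scan_sites(dna(s, "circular"), enz),
                       oracle_scan_circular(s, rec))
    }
  }
})

test_that("blunt digestion conserves length and counts fragments correctly", {
  # circular with n sites -> n fragments summing to the input length
  set.seed(13)
  for (i in 1:10) {
    core <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    s <- paste0("GATATC", core, "GATATC",
                paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
    n_sites <- length(scan_sites(dna(s, "circular"), "EcoRV"))
    frags <- blunt_digest(dna(s, "circular"), "EcoRV")
    expect_length(frags, n_sites)
    expect_identical(sum(vapply(frags, function(f) nchar(f$seq), integer(1))),
                     nchar(s))
    # concatenating fragments in cut order reproduces a rotation
    cat_seq <- paste(vapply(frags, `[[`, character(1), "seq"),
                     collapse = "")
    expect_true(grepl(cat_seq, paste0(s, s), fixed = TRUE))
  }
  # one site -> one full-length linear fragment
  one <- dna(paste0("GATATC", strrep("A", 20)), "circular")
  frags <- blunt_digest(one, "EcoRV")
  expect_length(frags, 1L)
  expect_identical(nchar(frags[[1]]$seq), 26L)
  expect_error(blunt_digest(dna(strrep("A", 30), "circular"), "EcoRV"),
               "no cut site for EcoRV")
  expect_error(blunt_digest(dna("GATATCAAA"), "XbaI"), "no defined cut")
})

test_that("a flanked device releases as a 154-nt fragment from a 100-nt payload", {
  kit <- fixture_kit()
  donor <- kit$donors[["pDonor_aadA_cass_syn"]]
  frags <- blunt_digest(donor$sequence, "EcoRV")
  expect_length(frags, 2L)
  lens <- vapply(frags, function(f) nchar(f$seq), integer(1))
  # per-end remnant: 3 (half site) + 15 (core) + 3 (GAT) + 6 (secondary)
  expect_true(154L %in% lens)
  expect_identical(sum(lens), nchar(donor$sequence$bases))
})

test_that("Wallace Tm follows the 2/4 rule and is strand-symmetric", {
  expect_identical(wallace_tm("GACGTC"), 20L)
  expect_identical(wallace_tm("GTCGGGGGCCCCCGGGGGGAT"), 78L)
  expect_identical(wallace_tm("TAGTCGGCCAATAACCCAGGGATTT"), 74L)
  set.seed(14)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:40, 1), TRUE),
               collapse = "")
    expect_identical(wallace_tm(s), wallace_tm(reverse_complement(s)))
  }
  expect_error(wallace_tm("A"), "too short")
})

test_that("nearest-neighbor Tm is available behind melting parameters", {
  p_nn <- melting_params("nearest_neighbor")
  tm <- melting_tm("ATCGGGGGCCCCCGGGGGGAT", p_nn)
  expect_true(is.numeric(tm) && tm > 50)
  expect_identical(melting_tm("GACGTC"), wallace_tm("GACGTC"))
  expect_error(melting_params(threshold_C = -1))
})

test_that("hairpin screen finds stems and reports their coordinates", {
  rep <- hairpin_screen("GGGGAAAACCCC")
  expect_false(rep$pass)
  expect_true(any(rep$stems$start5 == 1L & rep$stems$length >= 4L))
  expect_true(hairpin_screen("TAGTCGGCCAATAACCCAGGGATTT")$pass)
  expect_true(hairpin_screen("AAAAAAAAAA")$pass)
  # loop shorter than min_loop does not count as a hairpin
  expect_true(hairpin_screen("GGGGACCCC")$pass)
  expect_false(hairpin_screen("GGGGACCCC", min_loop = 1)$pass)
})
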