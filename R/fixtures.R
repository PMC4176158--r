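#' @name fixtures
#' @title Seeded synthetic fixture generation
#'
#' @description
#' Fabricates devices, donor plasmids and parts databases so the whole
#' system is exercisable without any sequence download. Payloads are drawn
#' base-by-base at a stated G+C fraction from R's Mersenne-Twister stream
#' under an explicit integer seed (the calling stream is saved and
#' restored), and resampled until free of EcoRV, ZraI and SwaI sites on
#' both strands (bounded retries). Identical seed and parameters give
#' byte-identical output.
NULL

with_rng <- function(seed, fn) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  fn()
}

random_bases <- function(n, gc_fraction = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                        gc_fraction / 2, (1 - gc_fraction) / 2)),
        collapse = "")
}

FORBIDDEN_SITES <- c("EcoRV", "ZraI", "SwaI")

site_free <- function(seqc, enzymes = FORBIDDEN_SITES) {
  all(vapply(enzymes, function(e)
    length(scan_sites(dna(seqc), e)) == 0L &&
      length(scan_sites(dna(rc_string(seqc)), e)) == 0L, logical(1)))
}

# random sequence free of the release/cassette enzyme sites
random_clean <- function(n, gc_fraction = 0.5, max_tries = 200L,
                         accept = site_free) {
  for (i in seq_len(max_tries)) {
    s <- random_bases(n, gc_fraction)
    if (accept(s)) return(s)
  }
  stop(sprintf("retry budget exhausted: no site-free sequence of %d nt found",
               n), call. = FALSE)
}

# payload = spacer1 + parts (in order, single spacers between) + spacer2;
# optionally plants one EcoRV site mid-spacer2 to force ZraI release
build_payload <- function(payload_length, gc_fraction, part_seqs,
                          internal_ecorv, max_tries = 200L) {
  plen <- sum(nchar(part_seqs))
  free <- payload_length - plen
  k <- length(part_seqs) + 1L             # number of spacers
  if (free < k * 2L + (if (internal_ecorv) 10L else 0L))
    stop("payload too short for the requested embedded parts",
         call. = FALSE)
  for (i in seq_len(max_tries)) {
    cuts <- if (k > 1L) sort(sample(seq_len(free - 1L), k - 1L)) else integer(0)
    lens <- diff(c(0L, cuts, free))
    if (any(lens < 2L)) next
    spacers <- vapply(lens, random_bases, character(1),
                      gc_fraction = gc_fraction)
    if (internal_ecorv) {
      sp <- spacers[k]
      if (nchar(sp) < 8L) next
      at <- max(1L, (nchar(sp) - 6L) %/% 2L)
      substr(sp, at, at + 5L) <- "GATATC"
      spacers[k] <- sp
    }
    pieces <- character(0)
    starts <- integer(length(part_seqs))
    pos <- 0L
    for (p in seq_len(k)) {
      pieces <- c(pieces, spacers[p])
      pos <- pos + nchar(spacers[p])
      if (p <= length(part_seqs)) {
        starts[p] <- pos + 1L
        pieces <- c(pieces, part_seqs[p])
        pos <- pos + nchar(part_seqs[p])
      }
    }
    payload <- paste(pieces, collapse = "")
    ok <- if (internal_ecorv) {
      length(scan_sites(dna(payload), "EcoRV")) == 1L &&
        length(scan_sites(dna(payload), "ZraI")) == 0L &&
        length(scan_sites(dna(payload), "SwaI")) == 0L
    } else site_free(payload)
    if (ok) return(list(payload = payload, part_starts = starts))
  }
  stop("retry budget exhausted while embedding parts in a payload",
       call. = FALSE)
}

#' Generate one synthetic device and its donor plasmid
#'
#' The payload is random at the stated G+C fraction, optionally embedding
#' part sequences (annotated with payload-relative coordinates) and
#' optionally planting a single internal EcoRV site so that
#' [choose_enzyme()] selects ZraI. The donor wraps the flanked device in a
#' synthetic circular backbone carrying a marker part. The generated
#' device always passes [validate_device()].
#'
#' @param seed Integer seed.
#' @param id Device id.
#' @param category Device category (not custom_pcr_fragment).
#' @param payload_length Payload length in nt (default 100).
#' @param gc_fraction Payload G+C fraction in `[0, 1]` (default 0.5).
#' @param parts Optional parts data.frame whose sequences are embedded in
#'   order.
#' @param internal_ecorv Plant one internal EcoRV site (forces ZraI
#'   release, mirroring devices whose sequence contains an EcoRV site).
#' @param backbone_length Donor backbone length (default 2700 nt).
#' @param backbone_marker Optional one-row parts data.frame embedded in
#'   the backbone.
#' @return List with `device` (`gc_device`) and `donor` (`gc_donor`).
#' @export
generate_device <- function(seed, id, category, payload_length = 100L,
                            gc_fraction = 0.5, parts = NULL,
                            internal_ecorv = FALSE,
                            backbone_length = 2700L,
                            backbone_marker = NULL) {
  with_rng(seed, function() {
    part_seqs <- if (!is.null(parts)) parts$sequence else character(0)
    built <- build_payload(payload_length, gc_fraction, part_seqs,
                           internal_ecorv)
    dparts <- if (!is.null(parts))
      data.frame(part_id = parts$id, start = built$part_starts,
                 end = built$part_starts + nchar(part_seqs) - 1L,
                 strand = "+", stringsAsFactors = FALSE)
    else empty_device_parts()
    device <- device_record(id, category, built$payload, parts = dparts)
    marker_seq <- if (!is.null(backbone_marker)) backbone_marker$sequence[1]
                  else ""
    stub <- backbone_length - nchar(marker_seq)
    backbone <- random_clean(stub %/% 2, gc_fraction)
    backbone <- paste0(backbone, marker_seq,
                       random_clean(stub - stub %/% 2, gc_fraction))
    # re-screen the junction-crossing windows of the composite backbone
    if (!site_free(backbone))
      backbone <- paste0(random_clean(stub %/% 2, gc_fraction), marker_seq,
                         random_clean(stub - stub %/% 2, gc_fraction))
    if (!site_free(backbone))
      stop("retry budget exhausted while building a donor backbone",
           call. = FALSE)
    list(device = device, donor = donor_plasmid(device, backbone))
  })
}

#' Generate a ccdB cloning-cassette device
#'
#' Payload layout: left 25-nt cassette adaptor, SwaI half-sites
#' regenerating two SwaI sites around a synthetic ccdB stand-in, then the
#' reverse complement of the right adaptor. Opening with SwaI drops the
#' ccdB piece and exposes the two 25-nt overlaps.
#'
#' @param seed Integer seed.
#' @param id Device id.
#' @param payload_length Total payload length (>= 70; default 100).
#' @param ccdb_id Part id recorded for the ccdB stand-in.
#' @return List with `device`, `donor`, and `ccdb` (the stand-in part row).
#' @export
generate_cassette_device <- function(seed, id, payload_length = 100L,
                                     ccdb_id = "ccdB_syn") {
  tails <- cassette_adaptors()
  fixed <- 2L * 25L + 8L
  ccdb_len <- payload_length - fixed
  if (ccdb_len < 12L)
    stop("payload too short for a cloning cassette", call. = FALSE)
  with_rng(seed, function() {
    for (i in seq_len(200L)) {
      ccdb <- random_bases(ccdb_len, 0.5)
      payload <- paste0(tails[["left"]], "AAAT", ccdb, "ATTT",
                        rc_string(tails[["right"]]))
      ok <- length(scan_sites(dna(payload), "EcoRV")) == 0L &&
        length(scan_sites(dna(payload), "ZraI")) == 0L &&
        length(scan_sites(dna(payload), "SwaI")) == 2L
      if (ok) {
        dparts <- data.frame(part_id = ccdb_id, start = 30L,
                             end = 29L + ccdb_len, strand = "+",
                             stringsAsFactors = FALSE)
        device <- device_record(id, "cloning_cassette", payload,
                                parts = dparts)
        backbone <- random_clean(2700L, 0.5)
        return(list(device = device,
                    donor = donor_plasmid(device, backbone),
                    ccdb = part_record(ccdb_id, "ccdB stand-in (synthetic)",
                                       "CDS", ccdb)))
      }
    }
    stop("retry budget exhausted while building a cloning cassette",
         call. = FALSE)
  })
}

#' Generate a complete four-device fixture kit
#'
#' One ZraI-released cyanobacterial replicon (with a planted internal
#' EcoRV site), an EcoRV-released E. coli origin, an EcoRV-released
#' antibiotic marker, and an EcoRV-released ccdB cloning cassette, each on
#' its own donor plasmid, plus a parts database covering every embedded
#' part. The four devices assemble into one circle with four junctions;
#' the two joints flanking the ZraI device each carry the single
#' half-site mismatch.
#'
#' @param seed Integer seed.
#' @param payload_length Payload length per device (default 100).
#' @return A `gc_catalog`.
#' @export
generate_fixture_kit <- function(seed = 1L, payload_length = 100L) {
  subseed <- function(i) (as.integer(seed) * 101L + i) %% .Machine$integer.max
  embedded_len <- max(20L, min(40L, payload_length %/% 2L - 10L))
  mk_part <- function(i, pid, role) with_rng(subseed(i), function()
    part_record(pid, paste0(pid, " (synthetic)"), role,
                random_clean(embedded_len, 0.5)))
  p_rep <- mk_part(11L, "repA_syn", "replicon")
  p_ori <- mk_part(12L, "oriV_syn", "replicon")
  p_mark <- mk_part(13L, "aadA_syn", "marker")
  p_amp <- with_rng(subseed(14L), function()
    part_record("ampR_syn", "ampR_syn (synthetic)", "marker",
                random_clean(200L, 0.5)))
  g1 <- generate_device(subseed(1L), "pDU1_syn", "cyano_replicon",
                        payload_length, parts = p_rep,
                        internal_ecorv = TRUE, backbone_marker = p_amp)
  g2 <- generate_device(subseed(2L), "oriEc_syn", "ecoli_origin_paired",
                        payload_length, parts = p_ori,
                        backbone_marker = p_amp)
  g3 <- generate_device(subseed(3L), "aadA_cass_syn", "antibiotic_marker",
                        payload_length, parts = p_mark,
                        backbone_marker = p_amp)
  g4 <- generate_cassette_device(subseed(4L), "ccdB_cass_syn",
                                 payload_length)
  catalog(devices = list(g1$device, g2$device, g3$device, g4$device),
          donors = list(g1$donor, g2$donor, g3$donor, g4$donor),
          parts = rbind(p_rep, p_ori, p_mark, p_amp, g4$ccdb))
}
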