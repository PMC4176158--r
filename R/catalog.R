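#' Device categories and their adaptor flank assignments
#'
#' Flank classes follow the published assignment: cyanobacterial replicons
#' and E. coli origins for knockout plasmids are flanked by G5C5 and C3G3;
#' E. coli origins to be paired with a cyanobacterial replicon by C3G3 and
#' GC; broad-host-range replicons and neutral sites by G5C5 and GC;
#' antibiotic markers by GC and C2G; and all functional modules
#' (cloning/expression/reporter cassettes, promoter-reporter modules) by
#' C2G and G5C5. Categories whose published table prints only one flank
#' take the missing face from the class assignment (always G5C5-XbaI /
#' XbaI-G5C5). Custom PCR fragments have no fixed faces; they acquire them
#' from their slot in a knockout plan.
#'
#' @return data.frame with columns `name`, `left_label`, `right_label`,
#'   `left_class`, `right_class`.
#' @export
device_categories <- function() {
  df <- data.frame(
    name = c("cyano_replicon", "ecoli_origin_knockout", "ecoli_origin_paired",
             "bhr_replicon", "neutral_site", "antibiotic_marker",
             "cloning_cassette", "expression_cassette", "reporter_cassette",
             "promoter_reporter", "custom_pcr_fragment"),
    left_label = c("G5C5-XbaI", "G5C5-XbaI", "C3G3-MfeI",
                   "G5C5-XbaI", "G5C5-XbaI", "GC-NheI",
                   "C2G-AgeI", "C2G-AgeI", "C2G-AgeI",
                   "C2G-AgeI", NA),
    right_label = c("SacI-C3G3", "SacI-C3G3", "NheI-GC",
                    "NheI-GC", "NheI-GC", "AgeI-C2G",
                    "XbaI-G5C5", "XbaI-G5C5", "XbaI-G5C5",
                    "XbaI-G5C5", NA),
    stringsAsFactors = FALSE)
  tab <- adaptor_label_table()
  df$left_class <- tab$class[match(df$left_label, tab$label)]
  df$right_class <- tab$class[match(df$right_label, tab$label)]
  df
}

functional_categories <- function() {
  c("cloning_cassette", "expression_cassette", "reporter_cassette",
    "promoter_reporter")
}

#' Pick the release enzyme for a device payload
#'
#' EcoRV is the default release enzyme; ZraI is used instead when an EcoRV
#' site is present within the device sequence. A payload carrying both
#' GATATC and GACGTC internally cannot be released intact by either enzyme.
#' Both strands are screened (a no-op for these palindromic sites, kept for
#' future non-palindromic registry entries).
#'
#' @param payload Linear sequence.
#' @return A `gc_enzyme` (EcoRV or ZraI).
#' @examples
#' choose_enzyme("AAATTTAAATTTAAA")$name            # EcoRV
#' choose_enzyme("AAAGATATCAAA")$name               # ZraI
#' @export
choose_enzyme <- function(payload) {
  bases <- seq_chars(payload)
  has_site <- function(enz) {
    length(scan_sites(bases, enz)) > 0L ||
      length(scan_sites(rc_string(bases), enz)) > 0L
  }
  if (!has_site("EcoRV")) return(as_enzyme("EcoRV"))
  if (!has_site("ZraI")) return(as_enzyme("ZraI"))
  stop("no compatible release enzyme: payload contains both EcoRV and ZraI sites",
       call. = FALSE)
}

#' Build a part record
#'
#' @param id,name Identifiers.
#' @param role One of promoter, RBS, CDS, terminator, replicon, marker, other.
#' @param sequence Part sequence.
#' @return One-row data.frame (rows are stacked into a parts database).
#' @export
part_record <- function(id, name = id,
                        role = c("other", "promoter", "RBS", "CDS",
                                 "terminator", "replicon", "marker"),
                        sequence) {
  role <- match.arg(role)
  data.frame(id = id, name = name, role = role,
             sequence = seq_chars(sequence), stringsAsFactors = FALSE)
}

empty_parts <- function() {
  data.frame(id = character(0), name = character(0), role = character(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

empty_device_parts <- function() {
  data.frame(part_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Build a device record
#'
#' A device is a categorized payload with two adaptor faces drawn from its
#' category's flank assignment. Both faces carry the device's single
#' release enzyme, chosen by [choose_enzyme()] unless supplied.
#'
#' @param id Device identifier.
#' @param category A [device_categories()] name (not custom_pcr_fragment).
#' @param payload Linear payload sequence (no internal release-enzyme site).
#' @param parts Optional data.frame of payload-relative part annotations
#'   (`part_id`, `start`, `end`, `strand`).
#' @param enzyme Optional release enzyme override.
#' @return A `gc_device`.
#' @export
device_record <- function(id, category, payload, parts = NULL, enzyme = NULL) {
  cats <- device_categories()
  i <- match(category, cats$name)
  if (is.na(i))
    stop(sprintf("unknown device category: %s", category), call. = FALSE)
  if (category == "custom_pcr_fragment")
    stop("custom PCR fragments take their faces from an assembly plan; use plan_knockout()",
         call. = FALSE)
  payload <- seq_chars(payload)
  enzyme <- if (is.null(enzyme)) choose_enzyme(payload) else as_enzyme(enzyme)
  if (is.null(parts)) parts <- empty_device_parts()
  structure(list(id = id, category = category,
                 payload = dna(payload, "linear"),
                 left_face = adaptor_face(cats$left_label[i], enzyme),
                 right_face = adaptor_face(cats$right_label[i], enzyme),
                 release_enzyme = enzyme$name,
                 parts = parts),
            class = "gc_device")
}

#' @export
print.gc_device <- function(x, ...) {
  cat(sprintf("<device> %s (%s), payload %d nt, faces %s | %s, release %s, %d part(s)\n",
              x$id, x$category, nchar(x$payload$bases),
              x$left_face$label, x$right_face$label, x$release_enzyme,
              nrow(x$parts)))
  invisible(x)
}

#' Validate a device record
#'
#' Collects rule violations instead of stopping: wrong flank classes for
#' the category, internal release-enzyme sites in the payload (positions
#' named), mismatched face enzymes, malformed flanks. An empty report means
#' the device is valid.
#'
#' @param d A `gc_device`.
#' @return A `gc_validation` report (list with `device`, `valid`,
#'   `violations` character vector).
#' @export
validate_device <- function(d) {
  v <- character(0)
  cats <- device_categories()
  i <- match(d$category, cats$name)
  if (is.na(i)) {
    v <- c(v, sprintf("unknown category: %s", d$category))
  } else if (d$category != "custom_pcr_fragment") {
    if (d$left_face$class != cats$left_class[i] ||
        d$right_face$class != cats$right_class[i])
      v <- c(v, sprintf(
        "flank class mismatch: category %s requires (%s, %s), device has (%s, %s)",
        d$category, cats$left_class[i], cats$right_class[i],
        d$left_face$class, d$right_face$class))
  }
  if (d$left_face$enzyme != d$right_face$enzyme)
    v <- c(v, sprintf("faces use different release enzymes (%s vs %s)",
                      d$left_face$enzyme, d$right_face$enzyme))
  if (d$left_face$enzyme != d$release_enzyme)
    v <- c(v, "face release enzyme disagrees with the device release enzyme")
  for (fc in list(d$left_face, d$right_face)) {
    ok <- tryCatch({ parse_flank(fc$flank); TRUE }, error = function(e) FALSE)
    if (!ok) v <- c(v, sprintf("flank %s does not parse", fc$label))
  }
  # internal release sites, both strands
  payload <- d$payload$bases
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") payload else rc_string(payload)
    hits <- scan_sites(dna(ss), d$release_enzyme)
    if (length(hits))
      v <- c(v, sprintf("payload contains %s site(s) at position(s) %s on strand %s",
                        d$release_enzyme, paste(hits, collapse = ","), strand))
  }
  if (nrow(d$parts)) {
    bad <- d$parts$start < 1L | d$parts$end > nchar(payload) |
      d$parts$start > d$parts$end
    if (any(bad))
      v <- c(v, sprintf("part annotation(s) out of payload bounds: %s",
                        paste(d$parts$part_id[bad], collapse = ",")))
  }
  structure(list(device = d$id, valid = length(v) == 0L, violations = v),
            class = "gc_validation")
}

#' @export
print.gc_validation <- function(x, ...) {
  if (x$valid) cat(sprintf("<validation> %s: valid\n", x$device))
  else cat(sprintf("<validation> %s: %d violation(s)\n  - %s\n",
                   x$device, length(x$violations),
                   paste(x$violations, collapse = "\n  - ")))
  invisible(x)
}

# device insert as it sits on the donor top strand:
# left flank verbatim, payload, right flank reverse-complemented (the right
# flank is stored as the bottom-strand string so its release site lies
# distal to the payload)
device_insert <- function(device) {
  paste0(device$left_face$flank, device$payload$bases,
         rc_string(device$right_face$flank))
}

#' Embed a device in a donor plasmid
#'
#' The donor is a circular sequence: backbone + left flank + payload +
#' right flank (bottom-strand orientation). Digestion with the device's
#' release enzyme must drop the device out as one intact fragment.
#'
#' @param device A `gc_device`.
#' @param backbone Backbone sequence (linear character or `gc_dna`); must be
#'   free of the device's release-enzyme site for a clean 2-fragment digest.
#' @param id Donor identifier (default derived from the device id).
#' @return A `gc_donor` (fields `id`, `device_id`, `sequence` circular).
#' @export
donor_plasmid <- function(device, backbone, id = paste0("pDonor_", device$id)) {
  seqc <- paste0(seq_chars(backbone), device_insert(device))
  donor <- structure(list(id = id, device_id = device$id,
                          sequence = dna(seqc, "circular")),
                     class = "gc_donor")
  frags <- blunt_digest(donor$sequence, device$release_enzyme)
  hit <- vapply(frags, function(f) grepl(device$payload$bases, f$seq,
                                         fixed = TRUE), logical(1))
  if (sum(hit) != 1L)
    stop(sprintf("donor %s: device payload is not released intact", id),
         call. = FALSE)
  donor
}

#' @export
print.gc_donor <- function(x, ...) {
  cat(sprintf("<donor plasmid> %s carrying %s, %d bp circular\n",
              x$id, x$device_id, nchar(x$sequence$bases)))
  invisible(x)
}

#' Assemble a catalog object
#'
#' @param devices List of `gc_device`.
#' @param donors List of `gc_donor`.
#' @param parts Parts database data.frame (see [part_record()]).
#' @return A `gc_catalog`.
#' @export
catalog <- function(devices = list(), donors = list(), parts = empty_parts()) {
  names(devices) <- vapply(devices, `[[`, character(1), "id")
  names(donors) <- vapply(donors, `[[`, character(1), "id")
  if (anyDuplicated(names(devices)))
    stop("duplicate device id in catalog", call. = FALSE)
  if (anyDuplicated(names(donors)))
    stop("duplicate donor id in catalog", call. = FALSE)
  if (anyDuplicated(parts$id))
    stop("duplicate part id in catalog", call. = FALSE)
  structure(list(devices = devices, donors = donors, parts = parts),
            class = "gc_catalog")
}

#' @export
print.gc_catalog <- function(x, ...) {
  cat(sprintf("<catalog> %d device(s), %d donor plasmid(s), %d part(s)\n",
              length(x$devices), length(x$donors), nrow(x$parts)))
  for (d in x$devices)
    cat(sprintf("  %s (%s, %d nt, %s)\n", d$id, d$category,
                nchar(d$payload$bases), d$release_enzyme))
  invisible(x)
}

# find the donor carrying a given device
donor_for_device <- function(cat_or_donors, device_id) {
  donors <- if (inherits(cat_or_donors, "gc_catalog")) cat_or_donors$donors
            else cat_or_donors
  for (dn in donors) if (dn$device_id == device_id) return(dn)
  stop(sprintf("no donor plasmid carries device %s", device_id),
       call. = FALSE)
}
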