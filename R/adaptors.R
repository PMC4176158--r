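#' The four GC-adaptor classes
#'
#' Each adaptor class is a 15-bp core of G and C bases only. The two
#' orientations of a class (core and its reverse complement) are distinct
#' strings for all four classes, which is what lets the cores dictate both
#' the order and the orientation of devices around the assembled circle.
#'
#' @return Named character vector of canonical (forward) 15-nt cores.
#' @examples
#' adaptor_classes()[["G5C5"]]
#' @export
adaptor_classes <- function() {
  c(G5C5 = "GGGGGCCCCCGGGGG",
    C3G3 = "GGGCCCGGGCCCGGG",
    GC   = "CGCGCGCGCGCGCGC",
    C2G  = "CGGCGGCGGCGGCGG")
}

# label -> (class, orientation of the core within the flank string,
# secondary enzyme, release enzyme as printed)
adaptor_label_table <- function() {
  data.frame(
    label = c("G5C5-XbaI", "SacI-C3G3", "C3G3-MfeI", "NheI-GC",
              "GC-NheI", "AgeI-C2G", "C2G-AgeI", "XbaI-G5C5"),
    class = c("G5C5", "C3G3", "C3G3", "GC", "GC", "C2G", "C2G", "G5C5"),
    orientation = c("forward", "forward", "revcomp", "forward",
                    "revcomp", "forward", "revcomp", "revcomp"),
    secondary = c("XbaI", "SacI", "MfeI", "NheI", "NheI", "AgeI", "AgeI",
                  "XbaI"),
    printed_enzyme = c("ZraI", "ZraI", "EcoRV", "EcoRV", "EcoRV", "EcoRV",
                       "EcoRV", "EcoRV"),
    stringsAsFactors = FALSE)
}

#' Bundled adaptor flank sequences
#'
#' The ten published 30-nt flank strings, uppercased, one row per printed
#' table entry (two labels recur across device categories, so there are
#' eight unique labels). Each flank decomposes as
#' release site (6) + core (15) + GAT half-site (3) + secondary site (6).
#'
#' @return data.frame with columns `label`, `category`, `enzyme` (release
#'   enzyme as printed), `flank` (30-nt string).
#' @examples
#' adaptor_flanks()
#' @export
adaptor_flanks <- function() {
  rows <- data.frame(
    label = c("G5C5-XbaI", "SacI-C3G3", "C3G3-MfeI", "NheI-GC",
              "G5C5-XbaI", "NheI-GC", "GC-NheI", "AgeI-C2G",
              "C2G-AgeI", "XbaI-G5C5"),
    category = c("cyano_replicon", "ecoli_origin_knockout",
                 "ecoli_origin_paired", "ecoli_origin_paired",
                 "bhr_replicon", "neutral_site",
                 "antibiotic_marker", "antibiotic_marker",
                 "cloning_cassette", "expression_cassette"),
    stringsAsFactors = FALSE)
  tab <- adaptor_label_table()
  idx <- match(rows$label, tab$label)
  rows$enzyme <- tab$printed_enzyme[idx]
  rows$flank <- vapply(idx, function(i) {
    face_flank(tab$class[i], tab$orientation[i], tab$secondary[i],
               tab$printed_enzyme[i])
  }, character(1))
  rows
}

face_flank <- function(class, orientation, secondary, enzyme) {
  core <- adaptor_classes()[[class]]
  if (orientation == "revcomp") core <- rc_string(core)
  paste0(as_enzyme(enzyme)$recognition, core, "GAT",
         as_enzyme(secondary)$recognition)
}

#' Construct an adaptor face from its published label
#'
#' @param label One of the eight flank labels (see [adaptor_flanks()]).
#' @param enzyme Release enzyme for this face; defaults to the enzyme the
#'   flank is printed with. A device's two faces must share one release
#'   enzyme, so the 6-nt release-site prefix of a face's flank follows the
#'   device's chosen enzyme rather than the printed default.
#' @return A `gc_face` object.
#' @examples
#' adaptor_face("G5C5-XbaI")
#' adaptor_face("NheI-GC", enzyme = "ZraI")
#' @export
adaptor_face <- function(label, enzyme = NULL) {
  tab <- adaptor_label_table()
  i <- match(label, tab$label)
  if (is.na(i))
    stop(sprintf("unknown adaptor label: %s", label), call. = FALSE)
  enzyme <- as_enzyme(if (is.null(enzyme)) tab$printed_enzyme[i] else enzyme)
  if (!enzyme$name %in% c("EcoRV", "ZraI"))
    stop("release enzyme must be EcoRV or ZraI", call. = FALSE)
  core <- adaptor_classes()[[tab$class[i]]]
  if (tab$orientation[i] == "revcomp") core <- rc_string(core)
  structure(list(label = tab$label[i],
                 class = tab$class[i],
                 orientation = tab$orientation[i],
                 core = core,
                 enzyme = enzyme$name,
                 secondary = tab$secondary[i],
                 flank = face_flank(tab$class[i], tab$orientation[i],
                                    tab$secondary[i], enzyme$name)),
            class = "gc_face")
}

#' @export
print.gc_face <- function(x, ...) {
  cat(sprintf("<adaptor face> %s: %s [%s %s, release %s, secondary %s]\n",
              x$label, x$flank, x$class, x$orientation, x$enzyme, x$secondary))
  invisible(x)
}

#' Parse a 30-nt adaptor flank string
#'
#' Decomposes a flank into release site (EcoRV/ZraI), 15-nt core matching
#' one adaptor class in one orientation, the literal GAT half-site, and a
#' known secondary restriction site. Case is not semantic (the published
#' table prints secondary sites in lowercase); input is uppercased.
#'
#' @param flank_string 30-character flank.
#' @return A `gc_face`.
#' @examples
#' parse_flank("GACGTCGGGGGCCCCCGGGGGGATtctaga")
#' @export
parse_flank <- function(flank_string) {
  bases <- seq_chars(flank_string)
  if (nchar(bases) != 30L)
    stop(sprintf("flank must be 30 nt, got %d", nchar(bases)), call. = FALSE)
  site <- substr(bases, 1L, 6L)
  enzyme <- switch(site, GATATC = "EcoRV", GACGTC = "ZraI",
                   stop(sprintf("unknown release site: %s", site),
                        call. = FALSE))
  core <- substr(bases, 7L, 21L)
  classes <- adaptor_classes()
  class <- orientation <- NULL
  for (nm in names(classes)) {
    if (core == classes[[nm]]) { class <- nm; orientation <- "forward"; break }
    if (core == rc_string(classes[[nm]])) {
      class <- nm; orientation <- "revcomp"; break
    }
  }
  if (is.null(class))
    stop(sprintf("core %s does not match any adaptor class", core),
         call. = FALSE)
  if (substr(bases, 22L, 24L) != "GAT")
    stop("missing GAT half-site after the core", call. = FALSE)
  sec <- substr(bases, 25L, 30L)
  reg <- enzymes()
  secondary <- NULL
  for (nm in c("XbaI", "SacI", "MfeI", "NheI", "AgeI")) {
    if (sec == reg[[nm]]$recognition) { secondary <- nm; break }
  }
  if (is.null(secondary))
    stop(sprintf("unknown secondary site: %s", sec), call. = FALSE)
  tab <- adaptor_label_table()
  hit <- tab$label[tab$class == class & tab$orientation == orientation &
                   tab$secondary == secondary]
  label <- if (length(hit) == 1L) hit
           else paste(class, orientation, secondary, sep = "/")
  structure(list(label = label, class = class, orientation = orientation,
                 core = core, enzyme = enzyme, secondary = secondary,
                 flank = bases),
            class = "gc_face")
}

#' Do two adaptor faces form a junction-compatible pair?
#'
#' TRUE when the faces belong to the same adaptor class and their stored
#' cores are mutual reverse complements. With the right flank of a device
#' stored on the bottom strand, this is exactly the condition under which
#' the released fragments present identical facing 21-mers (up to the
#' one-base half-site difference between EcoRV- and ZraI-released ends).
#'
#' @param left,right `gc_face` objects (or labels).
#' @return Logical scalar.
#' @examples
#' face_pairing(adaptor_face("G5C5-XbaI"), adaptor_face("XbaI-G5C5"))  # TRUE
#' face_pairing(adaptor_face("NheI-GC"), adaptor_face("AgeI-C2G"))     # FALSE
#' @export
face_pairing <- function(left, right) {
  left <- as_face(left)
  right <- as_face(right)
  left$class == right$class && left$core == rc_string(right$core)
}

as_face <- function(x) {
  if (inherits(x, "gc_face")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (nchar(x) == 30L) return(parse_flank(x))
    return(adaptor_face(x))
  }
  stop("expected a gc_face, an adaptor label, or a 30-nt flank string",
       call. = FALSE)
}

#' The 21-nt overlap contributed by an adaptor face
#'
#' After blunt release, a fragment end carries half-site + 15-nt core + GAT:
#' 21 nt in total. The half-site is ATC for EcoRV and GTC for ZraI, so the
#' EcoRV and ZraI versions of the same face differ at exactly position 1.
#'
#' @param face `gc_face` (or label).
#' @param enzyme Release enzyme, `"EcoRV"` or `"ZraI"`.
#' @return 21-character string.
#' @examples
#' junction_21mer(adaptor_face("G5C5-XbaI"), "EcoRV")
#' @export
junction_21mer <- function(face, enzyme) {
  face <- as_face(face)
  paste0(release_half_site(enzyme, "second"), face$core, "GAT")
}

#' The two published 25-nt cloning-cassette adaptors
#'
#' Free-form overlap adaptors used to clone a PCR fragment into a vector
#' backbone opened with SwaI at the ccdB cassette. Both end in ATTT, the
#' first half of the SwaI site, so the cassette regenerates SwaI sites on
#' insertion. Both have Wallace Tm >= 50 degC.
#'
#' @return Named character vector with elements `left` and `right`.
#' @export
cassette_adaptors <- function() {
  c(left  = "TAGTCGGCCAATAACCCAGGGATTT",
    right = "CTCCTGCCGGGGAGCTCCTTCATTT")
}
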