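#' Nucleotide sequence with explicit topology
#'
#' Light container for a DNA sequence over the strict alphabet A/C/G/T.
#' Lowercase input is uppercased; IUPAC ambiguity codes are rejected because
#' every downstream computation (site scanning, overlap matching, melting
#' temperature) assumes fully determined bases.
#'
#' @param bases Character scalar of bases (case-insensitive).
#' @param topology Either `"linear"` or `"circular"`.
#' @return An object of class `gc_dna` with fields `bases` and `topology`.
#' @examples
#' dna("gacgtc")
#' dna("ATCAAAAAAGAT", topology = "circular")
#' @export
dna <- function(bases, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  bases <- normalize_bases(bases)
  structure(list(bases = bases, topology = topology), class = "gc_dna")
}

normalize_bases <- function(bases) {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases))
    stop("'bases' must be a single character string", call. = FALSE)
  bases <- toupper(bases)
  if (!nzchar(bases))
    stop("sequence must be non-empty", call. = FALSE)
  bad <- gsub("[ACGT]", "", bases)
  if (nzchar(bad))
    stop(sprintf("invalid characters in sequence: %s",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  bases
}

#' @export
print.gc_dna <- function(x, ...) {
  n <- nchar(x$bases)
  shown <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<gc_dna> %s, %d nt: %s\n", x$topology, n, shown))
  invisible(x)
}

# Accept gc_dna or plain character everywhere internally.
seq_chars <- function(s) {
  if (inherits(s, "gc_dna")) return(s$bases)
  normalize_bases(s)
}

seq_topology <- function(s) {
  if (inherits(s, "gc_dna")) s$topology else "linear"
}

#' Reverse complement
#'
#' Watson-Crick reverse complement. Topology is preserved for `gc_dna`
#' input; plain character input returns character.
#'
#' @param s A `gc_dna` object or character scalar.
#' @return Same type as the input.
#' @examples
#' reverse_complement("GAT")            # "ATC"
#' reverse_complement("GACGTC")         # palindrome
#' @export
reverse_complement <- function(s) {
  bases <- seq_chars(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
  if (inherits(s, "gc_dna")) dna(rc, s$topology) else rc
}

#' Scan a sequence for a recognition site
#'
#' Reports every start position (1-based) of the enzyme's recognition
#' sequence on the top strand. For circular sequences, occurrences spanning
#' the origin are found by scanning the doubled sequence and reporting
#' positions modulo the length; palindromic sites are reported once per
#' locus (the top-strand scan already covers the bottom strand of a
#' palindrome).
#'
#' @param s Sequence (`gc_dna` or character; character is treated as linear).
#' @param enzyme A `gc_enzyme` or enzyme name known to [enzymes()].
#' @return Integer vector of 1-based start positions (possibly empty).
#' @examples
#' scan_sites("GATATC", "EcoRV")
#' scan_sites(dna("ATCAAAAAAGAT", "circular"), "EcoRV")  # spans the origin
#' @export
scan_sites <- function(s, enzyme) {
  enzyme <- as_enzyme(enzyme)
  bases <- seq_chars(s)
  L <- nchar(bases)
  rec <- enzyme$recognition
  if (nchar(rec) > L && seq_topology(s) == "linear") return(integer(0))
  subject <- if (seq_topology(s) == "circular") paste0(bases, bases) else bases
  hits <- Biostrings::start(
    Biostrings::matchPattern(rec, Biostrings::DNAString(subject)))
  if (seq_topology(s) == "circular") {
    hits <- sort(unique(hits[hits <= L]))
  }
  as.integer(hits)
}

#' Blunt digestion of a sequence
#'
#' Cuts at every recognition site of a blunt-cutting enzyme. A circular
#' sequence with n sites yields exactly n linear fragments whose lengths sum
#' to the input length; a linear sequence with n internal sites yields n + 1
#' fragments (used for simulated PCR amplicons carrying terminal adaptor
#' tails). Each fragment records the producing enzyme at the cut end(s);
#' native termini of a linear input are recorded as `NA`.
#'
#' @param s Sequence (`gc_dna`); circular for donor plasmids.
#' @param enzyme A cutting `gc_enzyme` (EcoRV, ZraI or SwaI) or its name.
#' @return List of fragments, each a list with `seq`, `left_enzyme`,
#'   `right_enzyme`.
#' @examples
#' frags <- blunt_digest(dna("GATATCAAAATTTTGATATCCCCGGG", "circular"), "EcoRV")
#' sum(vapply(frags, function(f) nchar(f$seq), integer(1)))  # length conserved
#' @export
blunt_digest <- function(s, enzyme) {
  enzyme <- as_enzyme(enzyme)
  if (!isTRUE(enzyme$cuts) || is.na(enzyme$cut_offset))
    stop(sprintf("enzyme %s has no defined cut position", enzyme$name),
         call. = FALSE)
  bases <- seq_chars(s)
  L <- nchar(bases)
  topo <- seq_topology(s)
  sites <- scan_sites(s, enzyme)
  if (length(sites) == 0L)
    stop(sprintf("no cut site for %s in the supplied sequence", enzyme$name),
         call. = FALSE)
  if (topo == "circular") {
    # cut falls between positions c and c+1 (c in 0..L-1; 0 wraps to L|1)
    cuts <- sort(unique((sites - 1L + enzyme$cut_offset) %% L))
    n <- length(cuts)
    doubled <- paste0(bases, bases)
    lapply(seq_len(n), function(i) {
      from <- cuts[i] + 1L
      to <- if (i < n) cuts[i + 1L] else cuts[1L] + L
      list(seq = substr(doubled, from, to),
           left_enzyme = enzyme$name, right_enzyme = enzyme$name)
    })
  } else {
    cuts <- sort(unique(sites - 1L + enzyme$cut_offset))
    cuts <- cuts[cuts >= 1L & cuts < L]
    bounds <- c(0L, cuts, L)
    lapply(seq_len(length(bounds) - 1L), function(i) {
      list(seq = substr(bases, bounds[i] + 1L, bounds[i + 1L]),
           left_enzyme = if (i == 1L) NA_character_ else enzyme$name,
           right_enzyme = if (i == length(bounds) - 1L) NA_character_
                          else enzyme$name)
    })
  }
}

#' Melting temperature by the Wallace rule
#'
#' Tm = 4 degC per G/C plus 2 degC per A/T. Deterministic integer
#' arithmetic; the default screen used for all adaptor overlaps.
#'
#' @param s Sequence (`gc_dna` linear or character), length >= 2.
#' @return Integer temperature in degrees Celsius.
#' @examples
#' wallace_tm("GACGTC")  # 20
#' @export
wallace_tm <- function(s) {
  bases <- seq_chars(s)
  if (nchar(bases) < 2L)
    stop("sequence too short for a melting temperature", call. = FALSE)
  counts <- table(factor(strsplit(bases, "")[[1]], levels = c("A", "C", "G", "T")))
  as.integer(4L * (counts[["G"]] + counts[["C"]]) +
             2L * (counts[["A"]] + counts[["T"]]))
}

#' Melting parameters
#'
#' @param method `"wallace"` (default) or `"nearest_neighbor"` (SantaLucia
#'   1998 unified parameters).
#' @param threshold_C Minimum acceptable overlap Tm in degC (default 50, the
#'   temperature of the isothermal assembly reaction).
#' @param monovalent_M Monovalent cation concentration for the
#'   nearest-neighbor method (mol/L).
#' @param strand_M Strand concentration for the nearest-neighbor method
#'   (mol/L).
#' @return A list of class `gc_melting_params`.
#' @export
melting_params <- function(method = c("wallace", "nearest_neighbor"),
                           threshold_C = 50,
                           monovalent_M = 0.05,
                           strand_M = 250e-12) {
  method <- match.arg(method)
  stopifnot(threshold_C > 0)
  structure(list(method = method, threshold_C = threshold_C,
                 monovalent_M = monovalent_M, strand_M = strand_M),
            class = "gc_melting_params")
}

#' Melting temperature under chosen parameters
#'
#' @param s Sequence.
#' @param params A [melting_params()] object.
#' @return Temperature in degC (integer for Wallace, numeric for
#'   nearest-neighbor).
#' @export
melting_tm <- function(s, params = melting_params()) {
  if (params$method == "wallace") wallace_tm(s)
  else nn_tm(s, monovalent_M = params$monovalent_M, strand_M = params$strand_M)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); keyed by top-strand dimer.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

nn_tm <- function(s, monovalent_M = 0.05, strand_M = 250e-12) {
  bases <- seq_chars(s)
  n <- nchar(bases)
  if (n < 2L)
    stop("sequence too short for a melting temperature", call. = FALSE)
  ch <- strsplit(bases, "")[[1]]
  dimers <- paste0(ch[-n], ch[-1])
  dh <- sum(.nn_dh[dimers])
  ds <- sum(.nn_ds[dimers])
  # initiation terms per terminal base
  for (b in ch[c(1, n)]) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(monovalent_M)
  1000 * dh / (ds + 1.98717 * log(strand_M / 4)) - 273.15
}

#' Screen a single strand for hairpin-forming stems
#'
#' Exhaustive substring scan: the screen fails when two reverse-complementary
#' substrings of length >= `min_stem` occur with at least `min_loop`
#' intervening bases (the minimum physical loop). Stems longer than
#' `min_stem` are detected through their length-`min_stem` seeds, which are
#' then extended maximally for the report. This is a conservative
#' design-time filter for custom overlap adaptors, not a thermodynamic
#' folding prediction.
#'
#' @param s Linear sequence.
#' @param min_stem Minimum paired stem length (nt).
#' @param min_loop Minimum intervening loop length (nt).
#' @return A list of class `gc_hairpin_report` with `pass` (logical) and
#'   `stems` (data.frame of stem coordinates: `start5`, `start3`, `length`).
#' @examples
#' hairpin_screen("GGGGAAAACCCC")            # fails: GGGG/CCCC stem
#' hairpin_screen("TAGTCGGCCAATAACCCAGGGATTT")  # passes
#' @export
hairpin_screen <- function(s, min_stem = 4L, min_loop = 3L) {
  bases <- seq_chars(s)
  if (seq_topology(s) != "linear")
    stop("hairpin screening applies to linear single strands", call. = FALSE)
  n <- nchar(bases)
  k <- as.integer(min_stem)
  stems <- list()
  if (n >= 2L * k + min_loop) {
    ch <- strsplit(bases, "")[[1]]
    subs <- vapply(seq_len(n - k + 1L),
                   function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
                   character(1))
    rcs <- vapply(subs, rc_string, character(1))
    for (i in seq_along(subs)) {
      jmin <- i + k + min_loop
      if (jmin > length(subs)) break
      js <- which(subs[jmin:length(subs)] == rcs[i]) + jmin - 1L
      for (j in js) {
        # extend the seed outward while bases keep pairing (the loop between
        # the inner stem edges is unchanged by outward extension)
        i0 <- i; j1 <- j + k - 1L; len <- k
        while (i0 > 1L && j1 < n &&
               rc_string(substr(bases, i0 - 1L, i0 - 1L)) ==
                 substr(bases, j1 + 1L, j1 + 1L)) {
          i0 <- i0 - 1L; j1 <- j1 + 1L; len <- len + 1L
        }
        stems[[length(stems) + 1L]] <-
          c(start5 = i0, start3 = j1 - len + 1L, length = len)
      }
    }
  }
  stems <- if (length(stems)) unique(as.data.frame(do.call(rbind, stems)))
           else data.frame(start5 = integer(0), start3 = integer(0),
                           length = integer(0))
  structure(list(pass = nrow(stems) == 0L, stems = stems,
                 min_stem = k, min_loop = as.integer(min_loop)),
            class = "gc_hairpin_report")
}

# fast base-R reverse complement for short internal strings
rc_string <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' @export
print.gc_hairpin_report <- function(x, ...) {
  cat(sprintf("<hairpin screen> %s (stem >= %d, loop >= %d)\n",
              if (x$pass) "PASS" else "FAIL", x$min_stem, x$min_loop))
  if (!x$pass) print(x$stems)
  invisible(x)
}
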