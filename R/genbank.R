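#' @name genbank
#' @title GenBank flat-file input and output
#'
#' @description
#' Minimal, lossless GenBank flat-file support for the record shapes this
#' package produces: LOCUS (name, length, topology), FEATURES with
#' arbitrary keys and qualifiers, and ORIGIN. Coordinates are 1-based
#' inclusive; a feature spanning the circular origin is written with the
#' `join(a..N,1..b)` convention and represented internally with
#' `end = N + b > N`. The LOCUS date is a fixed constant so that identical
#' inputs give byte-identical files.
#'
#' @param x For [write_genbank()]: a `gc_record`, `gc_plasmid`, or `gc_dna`.
#' @param path File path.
#' @param name Record name used in LOCUS when `x` carries none.
#' @return [read_genbank()] returns a `gc_record`: list with `name`,
#'   `sequence` (`gc_dna`), `features` (data.frame `key`, `start`, `end`,
#'   `strand`, `label`, plus a `qualifiers` list-column of named character
#'   vectors). [write_genbank()] returns `path` invisibly.
NULL

empty_features <- function() {
  data.frame(key = character(0), start = integer(0), end = integer(0),
             strand = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

gc_record <- function(name, sequence, features = NULL) {
  if (is.null(features)) features <- empty_features()
  if (is.null(features$qualifiers)) {
    features$qualifiers <- rep(list(character(0)), nrow(features))
  }
  structure(list(name = name, sequence = sequence, features = features),
            class = "gc_record")
}

#' @export
print.gc_record <- function(x, ...) {
  cat(sprintf("<genbank record> %s, %d bp %s, %d feature(s)\n", x$name,
              nchar(x$sequence$bases), x$sequence$topology, nrow(x$features)))
  invisible(x)
}

#' @rdname genbank
#' @export
write_genbank <- function(x, path, name = "record") {
  rec <- as_gc_record(x, name)
  seqc <- rec$sequence$bases
  L <- nchar(seqc)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2026",
            rec$name, L, rec$sequence$topology),
    "DEFINITION  .",
    "ACCESSION   .",
    "KEYWORDS    .",
    "SOURCE      synthetic DNA construct",
    "  ORGANISM  synthetic DNA construct",
    "FEATURES             Location/Qualifiers",
    sprintf("     %-15s %s", "source", sprintf("1..%d", L))
  )
  ft <- rec$features
  for (i in seq_len(nrow(ft))) {
    loc <- if (ft$end[i] > L)
      sprintf("join(%d..%d,1..%d)", ft$start[i], L, ft$end[i] - L)
    else sprintf("%d..%d", ft$start[i], ft$end[i])
    if (identical(ft$strand[i], "-")) loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, sprintf("     %-15s %s", ft$key[i], loc))
    quals <- character(0)
    if (!is.na(ft$label[i]) && nzchar(ft$label[i]))
      quals <- c(quals, sprintf("/label=\"%s\"", ft$label[i]))
    extra <- if (!is.null(ft$qualifiers)) ft$qualifiers[[i]] else character(0)
    if (length(extra))
      quals <- c(quals, sprintf("/%s=\"%s\"", names(extra), unname(extra)))
    for (q in quals)
      lines <- c(lines, paste0(strrep(" ", 21), q))
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(seqc)
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(low, s, min(s + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

as_gc_record <- function(x, name = "record") {
  if (inherits(x, "gc_record")) return(x)
  if (inherits(x, "gc_plasmid"))
    return(gc_record(x$id, x$sequence, x$features))
  if (inherits(x, "gc_dna")) return(gc_record(name, x))
  if (is.character(x) && length(x) == 1L) return(gc_record(name, dna(x)))
  stop("cannot interpret object as a GenBank record", call. = FALSE)
}

#' @rdname genbank
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L)
    stop("malformed GenBank record: missing LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]]
  name <- toks[1]
  topology <- if (any(toks == "circular")) "circular" else "linear"
  feat_at <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  end_at <- grep("^//", lines)
  if (length(origin_at) != 1L || length(end_at) < 1L)
    stop("malformed GenBank record: missing ORIGIN/terminator", call. = FALSE)
  seq_lines <- lines[(origin_at + 1L):(end_at[1] - 1L)]
  seqc <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- dna(seqc, topology)
  L <- nchar(seqc)

  rows <- list()
  if (length(feat_at) == 1L && feat_at < origin_at) {
    block <- lines[(feat_at + 1L):(origin_at - 1L)]
    cur <- NULL
    flush <- function(cur, rows) {
      if (is.null(cur) || cur$key == "source") return(rows)
      rows[[length(rows) + 1L]] <- cur
      rows
    }
    for (ln in block) {
      if (grepl("^     [^ ]", ln)) {           # new feature line
        rows <- flush(cur, rows)
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        if (grepl("^join\\(", loc)) {
          inner <- sub("^join\\((.*)\\)$", "\\1", loc)
          pieces <- strsplit(inner, ",")[[1]]
          a <- as.integer(strsplit(pieces[1], "\\.\\.")[[1]])
          b <- as.integer(strsplit(pieces[2], "\\.\\.")[[1]])
          start <- a[1]; end <- L + b[2]
        } else {
          ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
          start <- ab[1]; end <- ab[length(ab)]
        }
        cur <- list(key = key, start = start, end = end, strand = strand,
                    label = NA_character_, qualifiers = character(0))
      } else if (grepl("^ {21}/", ln) && !is.null(cur)) {
        q <- sub("^ +/", "", ln)
        qname <- sub("=.*$", "", q)
        qval <- if (grepl("=", q)) gsub("^\"|\"$", "", sub("^[^=]*=", "", q))
                else ""
        if (qname == "label") cur$label <- qval
        else {
          qs <- cur$qualifiers
          qs[[qname]] <- qval
          cur$qualifiers <- qs
        }
      }
    }
    rows <- flush(cur, rows)
  }
  features <- if (length(rows)) {
    df <- data.frame(
      key = vapply(rows, `[[`, character(1), "key"),
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "end"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      label = vapply(rows, `[[`, character(1), "label"),
      stringsAsFactors = FALSE)
    df$qualifiers <- lapply(rows, `[[`, "qualifiers")
    df
  } else {
    df <- empty_features()
    df$qualifiers <- list()
    df
  }
  gc_record(name, sequence, features)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or named list of `gc_dna`/character.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) seqs <- vapply(seqs, seq_chars, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("[[:space:]].*$", "", names(set))
  out
}
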