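#' @name catalog_io
#' @title Catalog manifest input and output
#'
#' @description
#' The catalog is serialized as one JSON manifest (versioned, structurally
#' validated on load) listing parts, devices and donor plasmids. Sequences
#' longer than 200 nt are stored as sibling GenBank files referenced from
#' the manifest, so the on-disk catalog stays diff-able; shorter sequences
#' are inlined. Serialization is canonical (fixed key order, records sorted
#' by id, fixed GenBank date), so load -> save -> load is byte-identical.
#'
#' @param path Manifest path (`.json`); sibling `.gb` files live next to it.
#' @param x A `gc_catalog`.
#' @param validate Validate every device on load (default TRUE; violations
#'   are an error).
#' @param inline_max Longest sequence stored inline (nt).
#' @return [load_catalog()] returns a `gc_catalog`; [save_catalog()]
#'   returns `path` invisibly.
NULL

MANIFEST_FORMAT <- "gcassembly-catalog"
MANIFEST_VERSION <- 1L

#' @rdname catalog_io
#' @export
save_catalog <- function(x, path, inline_max = 200L) {
  stopifnot(inherits(x, "gc_catalog"))
  dir <- dirname(path)
  devices <- lapply(x$devices[order(names(x$devices))], function(d) {
    payload <- d$payload$bases
    entry <- list(id = d$id, category = d$category,
                  release_enzyme = d$release_enzyme)
    if (nchar(payload) <= inline_max) {
      entry$payload <- payload
    } else {
      file <- paste0(d$id, ".gb")
      ft <- if (nrow(d$parts))
        data.frame(key = "misc_feature", start = d$parts$start,
                   end = d$parts$end, strand = d$parts$strand,
                   label = d$parts$part_id, stringsAsFactors = FALSE)
      else NULL
      write_genbank(gc_record(d$id, dna(payload), ft), file.path(dir, file))
      entry$payload_file <- file
    }
    entry$parts <- if (nrow(d$parts))
      d$parts[, c("part_id", "start", "end", "strand")]
    else empty_device_parts()
    entry
  })
  donors <- lapply(x$donors[order(names(x$donors))], function(dn) {
    entry <- list(id = dn$id, device_id = dn$device_id)
    if (nchar(dn$sequence$bases) <= inline_max) {
      entry$sequence <- dn$sequence$bases
    } else {
      file <- paste0(dn$id, ".gb")
      write_genbank(gc_record(dn$id, dn$sequence), file.path(dir, file))
      entry$sequence_file <- file
    }
    entry
  })
  parts <- x$parts[order(x$parts$id), , drop = FALSE]
  manifest <- list(format = MANIFEST_FORMAT, version = MANIFEST_VERSION,
                   parts = parts, devices = unname(devices),
                   donor_plasmids = unname(donors))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

require_fields <- function(obj, fields, what) {
  missing <- setdiff(fields, names(obj))
  if (length(missing))
    stop(sprintf("manifest schema violation: %s missing field(s) %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}

#' @rdname catalog_io
#' @export
load_catalog <- function(path, validate = TRUE) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  require_fields(manifest, c("format", "version", "parts", "devices",
                             "donor_plasmids"), "manifest")
  if (!identical(manifest$format, MANIFEST_FORMAT))
    stop(sprintf("manifest schema violation: format is %s, expected %s",
                 manifest$format, MANIFEST_FORMAT), call. = FALSE)
  if (manifest$version != MANIFEST_VERSION)
    stop(sprintf("unsupported manifest version: %s", manifest$version),
         call. = FALSE)
  dir <- dirname(path)
  read_ref <- function(entry, inline_field, file_field, what) {
    if (!is.null(entry[[inline_field]])) return(entry[[inline_field]])
    if (!is.null(entry[[file_field]])) {
      fp <- file.path(dir, entry[[file_field]])
      if (!file.exists(fp))
        stop(sprintf("missing referenced file for %s: %s", what, fp),
             call. = FALSE)
      return(read_genbank(fp)$sequence$bases)
    }
    stop(sprintf("manifest schema violation: %s has neither inline sequence nor file reference",
                 what), call. = FALSE)
  }
  parts <- if (length(manifest$parts)) {
    do.call(rbind, lapply(manifest$parts, function(p) {
      require_fields(p, c("id", "name", "role", "sequence"), "part")
      part_record(p$id, p$name, p$role, p$sequence)
    }))
  } else empty_parts()
  devices <- lapply(manifest$devices, function(e) {
    require_fields(e, c("id", "category", "release_enzyme"),
                   sprintf("device %s", e$id %||% "?"))
    payload <- read_ref(e, "payload", "payload_file",
                        sprintf("device %s", e$id))
    dparts <- if (length(e$parts)) {
      do.call(rbind, lapply(e$parts, function(p)
        data.frame(part_id = p$part_id, start = as.integer(p$start),
                   end = as.integer(p$end), strand = p$strand,
                   stringsAsFactors = FALSE)))
    } else empty_device_parts()
    device_record(e$id, e$category, payload, parts = dparts,
                  enzyme = e$release_enzyme)
  })
  donors <- lapply(manifest$donor_plasmids, function(e) {
    require_fields(e, c("id", "device_id"), sprintf("donor %s", e$id %||% "?"))
    seqc <- read_ref(e, "sequence", "sequence_file",
                     sprintf("donor %s", e$id))
    structure(list(id = e$id, device_id = e$device_id,
                   sequence = dna(seqc, "circular")),
              class = "gc_donor")
  })
  cat <- catalog(devices, donors, parts)
  if (validate) {
    for (d in cat$devices) {
      rep <- validate_device(d)
      if (!rep$valid)
        stop(sprintf("device %s failed validation on load:\n  %s", d$id,
                     paste(rep$violations, collapse = "\n  ")),
             call. = FALSE)
    }
    for (dn in cat$donors) {
      if (is.null(cat$devices[[dn$device_id]]))
        stop(sprintf("donor %s references unknown device %s", dn$id,
                     dn$device_id), call. = FALSE)
    }
  }
  cat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a device record from a GenBank record
#'
#' The record must carry the 30-nt adaptor flanks at its termini (the left
#' flank verbatim, the right flank as the reverse complement of its stored
#' string); the payload is the interior and record features become part
#' annotations with payload-relative coordinates.
#'
#' @param record A `gc_record` (from [read_genbank()]) or a GenBank path.
#' @param category Device category.
#' @return A `gc_device`.
#' @export
device_from_genbank <- function(record, category) {
  if (is.character(record)) record <- read_genbank(record)
  seqc <- record$sequence$bases
  L <- nchar(seqc)
  if (L < 61L)
    stop("record too short to carry two 30-nt flanks and a payload",
         call. = FALSE)
  left <- tryCatch(parse_flank(substr(seqc, 1L, 30L)), error = function(e)
    stop(sprintf("left flank does not parse: %s", conditionMessage(e)),
         call. = FALSE))
  right <- tryCatch(parse_flank(rc_string(substr(seqc, L - 29L, L))),
                    error = function(e)
    stop(sprintf("right flank does not parse: %s", conditionMessage(e)),
         call. = FALSE))
  payload <- substr(seqc, 31L, L - 30L)
  ft <- record$features
  inside <- ft$start >= 31L & ft$end <= L - 30L
  parts <- if (any(inside))
    data.frame(part_id = ft$label[inside], start = ft$start[inside] - 30L,
               end = ft$end[inside] - 30L, strand = ft$strand[inside],
               stringsAsFactors = FALSE)
  else empty_device_parts()
  d <- device_record(record$name, category, payload, parts = parts,
                     enzyme = left$enzyme)
  # the record's own flanks must agree with the category assignment
  if (d$left_face$class != left$class || d$right_face$class != right$class)
    stop(sprintf(
      "record flanks (%s, %s) do not match category %s assignment (%s, %s)",
      left$class, right$class, category, d$left_face$class,
      d$right_face$class), call. = FALSE)
  d
}

#' Read a parts database from TSV
#'
#' Expected columns: `id`, `name`, `role`, `sequence` (tab-separated, with
#' header).
#'
#' @param path TSV file.
#' @return Parts data.frame.
#' @export
read_parts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_fields(df, c("id", "name", "role", "sequence"), "parts TSV")
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    part_record(df$id[i], df$name[i], df$role[i], df$sequence[i])))
}

#' Write a parts database to TSV
#'
#' @param parts Parts data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parts_tsv <- function(parts, path) {
  utils::write.table(parts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a parts database from FASTA
#'
#' Headers follow `>id|role|name`; role defaults to `other` when absent.
#'
#' @param path FASTA file.
#' @return Parts data.frame.
#' @export
read_parts_fasta <- function(path) {
  seqs <- read_fasta(path)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    fields <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    part_record(fields[1],
                name = if (length(fields) >= 3) fields[3] else fields[1],
                role = if (length(fields) >= 2) fields[2] else "other",
                sequence = seqs[[i]])
  }))
}
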