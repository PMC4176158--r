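#' Annotate a plasmid from a parts database
#'
#' Reports every exact occurrence of every part on both strands of the
#' sequence. For circular sequences the scan crosses the origin
#' (origin-spanning features get `end > length`, written with the
#' `join()` convention on export). Overlapping hits and duplicate part
#' sequences are all reported; no arbitrary winner is chosen.
#'
#' @param x Sequence (`gc_dna`, `gc_plasmid`, `gc_record`, or character).
#' @param parts Parts database data.frame (`id`, `name`, `role`,
#'   `sequence`).
#' @return Features data.frame (`key`, `start`, `end`, `strand`, `label`),
#'   sorted by position.
#' @export
annotate_with_parts <- function(x, parts) {
  s <- if (inherits(x, "gc_plasmid") || inherits(x, "gc_record")) x$sequence
       else if (inherits(x, "gc_dna")) x else dna(x)
  bases <- s$bases
  L <- nchar(bases)
  circular <- s$topology == "circular"
  subject <- Biostrings::DNAString(if (circular) paste0(bases, bases)
                                   else bases)
  rows <- list()
  for (r in seq_len(nrow(parts))) {
    pseq <- parts$sequence[r]
    if (nchar(pseq) > L) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pseq else rc_string(pseq)
      starts <- Biostrings::start(Biostrings::matchPattern(pat, subject))
      if (circular) starts <- starts[starts <= L]
      for (st in starts) {
        rows[[length(rows) + 1L]] <- data.frame(
          key = part_feature_key(parts$role[r]),
          start = st, end = st + nchar(pseq) - 1L, strand = strand,
          label = parts$id[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_features())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map part roles onto conventional GenBank feature keys
part_feature_key <- function(role) {
  switch(role,
         promoter = "promoter",
         RBS = "RBS",
         CDS = "CDS",
         terminator = "terminator",
         replicon = "rep_origin",
         "misc_feature")
}
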