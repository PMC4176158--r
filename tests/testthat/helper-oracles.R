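# Independent brute-force oracles, kept deliberately separate from the
# package implementation paths they check.

# reverse complement via chartr + rev
oracle_rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# circular site scan: linear scan of every rotation, keeping sites that
# start at the rotation's first position
oracle_scan_circular <- function(s, recognition) {
  n <- nchar(s)
  hits <- integer(0)
  for (r in 0:(n - 1)) {
    rot <- paste0(substr(s, r + 1, n), substr(s, 1, r))
    if (substr(rot, 1, nchar(recognition)) == recognition)
      hits <- c(hits, r + 1L)
  }
  hits
}

# naive annotation scan with sequence doubling for circularity
oracle_annotate <- function(seqc, circular, part) {
  subject <- if (circular) paste0(seqc, seqc) else seqc
  L <- nchar(seqc)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") part else oracle_rc(part)
    np <- nchar(pat)
    limit <- if (circular) L else L - np + 1L
    for (st in seq_len(max(0L, limit)))
      if (substr(subject, st, st + np - 1L) == pat)
        out[[length(out) + 1L]] <- c(start = st, end = st + np - 1L,
                                     strand = strand)
  }
  out
}

# exhaustive circular-assembly search: fix fragment 1 forward, try every
# permutation and orientation of the rest; a joint is valid when the
# 21-nt terminal windows agree with at most one mismatch
oracle_count_circles <- function(frag_seqs, overlap = 21L,
                                 max_mismatch = 1L) {
  n <- length(frag_seqs)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  joint_ok <- function(a, b) {
    sa <- strsplit(substr(a, nchar(a) - overlap + 1L, nchar(a)), "")[[1]]
    sb <- strsplit(substr(b, 1L, overlap), "")[[1]]
    sum(sa != sb) <= max_mismatch
  }
  count <- 0L
  for (ord in perms(seq_len(n)[-1])) {
    order_full <- c(1L, ord)
    for (mask in 0:(2^(n - 1) - 1)) {
      flips <- c(FALSE, as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 2)), 1L)))
      seqs <- mapply(function(i, fl)
        if (fl) oracle_rc(frag_seqs[[i]]) else frag_seqs[[i]],
        order_full, flips)
      ok <- TRUE
      for (k in seq_len(n)) {
        a <- seqs[[k]]
        b <- seqs[[if (k == n) 1L else k + 1L]]
        if (!joint_ok(a, b)) { ok <- FALSE; break }
      }
      if (ok) count <- count + 1L
    }
  }
  count
}
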