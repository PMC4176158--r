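#' Bundled restriction enzyme registry
#'
#' The assembly scheme standardizes a small set of enzymes. Three blunt
#' cutters are modeled with cut positions: EcoRV (GAT^ATC), ZraI (GAC^GTC)
#' and SwaI (ATTT^AAAT, used to open the ccdB cloning cassette). Five more
#' sites appear only as the distal "secondary" site of an adaptor flank
#' (kept for later conventional re-cloning) and are registered site-only,
#' with no cut position: XbaI, SacI, MfeI, NheI, AgeI. All bundled
#' recognition sequences are palindromic.
#'
#' @return Named list of `gc_enzyme` objects.
#' @examples
#' enzymes()$EcoRV
#' @export
enzymes <- function() {
  spec <- list(
    # name        recognition  offset  cuts
    list("EcoRV", "GATATC",   3L,     TRUE),
    list("ZraI",  "GACGTC",   3L,     TRUE),
    list("SwaI",  "ATTTAAAT", 4L,     TRUE),
    list("XbaI",  "TCTAGA",   NA_integer_, FALSE),
    list("SacI",  "GAGCTC",   NA_integer_, FALSE),
    list("MfeI",  "CAATTG",   NA_integer_, FALSE),
    list("NheI",  "GCTAGC",   NA_integer_, FALSE),
    list("AgeI",  "ACCGGT",   NA_integer_, FALSE)
  )
  out <- lapply(spec, function(x)
    structure(list(name = x[[1]], recognition = x[[2]],
                   cut_offset = x[[3]], cuts = x[[4]]),
              class = "gc_enzyme"))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Look up an enzyme by name
#'
#' @param x A `gc_enzyme` (returned as-is) or an enzyme name.
#' @return A `gc_enzyme`.
#' @export
as_enzyme <- function(x) {
  if (inherits(x, "gc_enzyme")) return(x)
  reg <- enzymes()
  if (!is.character(x) || length(x) != 1L || !x %in% names(reg))
    stop(sprintf("unknown enzyme: %s", paste(x, collapse = ",")), call. = FALSE)
  reg[[x]]
}

#' @export
print.gc_enzyme <- function(x, ...) {
  cut <- if (isTRUE(x$cuts))
    paste0(substr(x$recognition, 1, x$cut_offset), "^",
           substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  else paste0(x$recognition, " (site only)")
  cat(sprintf("<enzyme> %s %s\n", x$name, cut))
  invisible(x)
}

# second half of a blunt release site, as left on a fragment's 5' end
# (EcoRV -> ATC, ZraI -> GTC); first half (GAT/GAC) remains at 3' ends
release_half_site <- function(enzyme, half = c("second", "first")) {
  enzyme <- as_enzyme(enzyme)
  half <- match.arg(half)
  if (!enzyme$name %in% c("EcoRV", "ZraI"))
    stop(sprintf("unsupported release enzyme: %s", enzyme$name), call. = FALSE)
  if (half == "second")
    substr(enzyme$recognition, enzyme$cut_offset + 1L, 6L)
  else
    substr(enzyme$recognition, 1L, enzyme$cut_offset)
}
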