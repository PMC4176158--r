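#' Generate the bench protocol for an assembly plan
#'
#' Donor plasmids are pooled by release enzyme and digested together
#' (5 U of enzyme per microgram of plasmid DNA, 3 to 5 h, final volume at
#' least 50 times the enzyme volume), digests are cleaned up with a DNA
#' clean-up/concentration kit, and fragments are joined by isothermal
#' assembly at 50 degC. Custom fragments are listed as PCR inputs with
#' their tailed primers. Reaction volumes and DNA masses beyond the quoted
#' rules are laboratory-adjustable placeholders.
#'
#' @param plan A `gc_plan`.
#' @param donors Optional donor list or `gc_catalog`; when given, pools
#'   name donor plasmids, otherwise they name devices.
#' @return A `gc_protocol` (renderable with `format()`/`print()`).
#' @export
generate_protocol <- function(plan, donors = NULL) {
  if (!length(plan$slots)) stop("empty assembly plan", call. = FALSE)
  device_slots <- Filter(function(s) s$kind == "device", plan$slots)
  custom_slots <- Filter(function(s) s$kind == "custom", plan$slots)
  pool_names <- vapply(device_slots, function(s) {
    if (!is.null(donors))
      donor_for_device(donors, s$device$id)$id
    else s$device$id
  }, character(1))
  pool_enzymes <- vapply(device_slots, slot_enzyme, character(1))
  pools <- split(pool_names, pool_enzymes)
  structure(list(
    vector_type = plan$vector_type,
    pools = pools,
    custom = lapply(custom_slots, function(s)
      list(id = s$id, enzyme = s$enzyme, primers = s$primers)),
    digestion = list(units_per_ug = 5, duration_h = c(3, 5),
                     min_volume_multiple = 50, temperature_C = 37),
    assembly_temperature_C = 50),
    class = "gc_protocol")
}

#' @export
format.gc_protocol <- function(x, ...) {
  lines <- c(sprintf("Assembly protocol (%s vector)", x$vector_type), "")
  step <- 1L
  lines <- c(lines, sprintf("%d. Restriction release", step))
  i <- 1L
  for (enz in names(x$pools)) {
    lines <- c(lines, sprintf("   Pool %d (%s): %s", i, enz,
                              paste(x$pools[[enz]], collapse = ", ")))
    i <- i + 1L
  }
  lines <- c(lines,
    sprintf("   Digest each pool with %g U of enzyme per ug of plasmid DNA for %g to %g h at %g C,",
            x$digestion$units_per_ug, x$digestion$duration_h[1],
            x$digestion$duration_h[2], x$digestion$temperature_C),
    sprintf("   in a final volume at least %gx the volume of enzyme added.",
            x$digestion$min_volume_multiple),
    "   [DNA mass and reaction volume are laboratory-adjustable.]")
  if (length(x$custom)) {
    step <- step + 1L
    lines <- c(lines, "", sprintf("%d. PCR of custom fragments", step))
    for (cf in x$custom) {
      lines <- c(lines,
        sprintf("   %s (digest the amplicon with %s before assembly):",
                cf$id, cf$enzyme),
        sprintf("     fwd 5'-%s-3'", cf$primers$forward),
        sprintf("     rev 5'-%s-3'", cf$primers$reverse))
    }
  }
  step <- step + 1L
  lines <- c(lines, "",
    sprintf("%d. Clean-up: purify and concentrate the digests with a DNA clean-up/concentration kit.",
            step))
  step <- step + 1L
  lines <- c(lines, "",
    sprintf("%d. Isothermal assembly: combine the released fragments and incubate the assembly reaction at %g C.",
            step, x$assembly_temperature_C))
  lines
}

#' @export
print.gc_protocol <- function(x, ...) {
  cat(paste(format(x), collapse = "\n"), "\n")
  invisible(x)
}
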