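#' Write an assembly plan to JSON
#'
#' Device slots are stored by id (resolved against a catalog on read);
#' custom slots carry their sequence, face labels, release enzyme and
#' target-specific primers inline.
#'
#' @param plan A `gc_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  slots <- lapply(plan$slots, function(s) {
    if (s$kind == "device")
      list(slot = s$slot, kind = "device", device_id = s$device$id)
    else
      list(slot = s$slot, kind = "custom", id = s$id,
           sequence = s$sequence, left_label = s$left_face$label,
           right_label = s$right_face$label, enzyme = s$enzyme,
           target_fwd = s$primers$target_fwd,
           target_rev = s$primers$target_rev)
  })
  jsonlite::write_json(list(format = "gcassembly-plan", version = 1L,
                            vector_type = plan$vector_type,
                            slots = slots),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an assembly plan from JSON
#'
#' @param path Plan JSON path.
#' @param catalog `gc_catalog` used to resolve device ids.
#' @return A `gc_plan` (re-validated against the adaptor grammar).
#' @export
read_plan <- function(path, catalog) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  require_fields(obj, c("format", "vector_type", "slots"), "plan")
  if (!identical(obj$format, "gcassembly-plan"))
    stop("not a gcassembly plan file", call. = FALSE)
  slots <- lapply(obj$slots, function(s) {
    if (s$kind == "device") {
      d <- catalog$devices[[s$device_id]]
      if (is.null(d))
        stop(sprintf("plan references unknown device %s", s$device_id),
             call. = FALSE)
      list(slot = s$slot, kind = "device", device = d)
    } else {
      lf <- adaptor_face(s$left_label, s$enzyme)
      rf <- adaptor_face(s$right_label, s$enzyme)
      list(slot = s$slot, kind = "custom", id = s$id,
           sequence = normalize_bases(s$sequence),
           left_face = lf, right_face = rf, enzyme = s$enzyme,
           primers = design_tailed_primers(s$target_fwd, s$target_rev,
                                           lf, rf, s$enzyme))
    }
  })
  new_plan(obj$vector_type, slots)
}
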