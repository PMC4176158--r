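#' Vector-type grammars
#'
#' Each shuttle-vector type is an ordered circular arrangement of device
#' categories whose adaptor classes chain head-to-tail: a self-replicating
#' strain-specific plasmid takes four devices (cyanobacterial replicon,
#' paired E. coli origin, antibiotic marker, functional module);
#' broad-host-range and neutral-site vectors take three (the replicon or
#' homology device carries its own E. coli origin); a knockout vector takes
#' two devices (E. coli origin designed for knockouts, antibiotic marker)
#' plus two custom PCR fragments carrying homology to the target.
#'
#' @return Named list of templates with `slots` (circular order),
#'   `n_devices`, `n_custom`.
#' @export
vector_templates <- function() {
  list(
    self_replicating_strain_specific = list(
      slots = c("cyano_replicon", "ecoli_origin_paired",
                "antibiotic_marker", "functional"),
      n_devices = 4L, n_custom = 0L),
    broad_host_range = list(
      slots = c("bhr_replicon", "antibiotic_marker", "functional"),
      n_devices = 3L, n_custom = 0L),
    neutral_site_integration = list(
      slots = c("neutral_site", "antibiotic_marker", "functional"),
      n_devices = 3L, n_custom = 0L),
    knockout = list(
      slots = c("ecoli_origin_knockout", "custom_upstream",
                "antibiotic_marker", "custom_downstream"),
      n_devices = 2L, n_custom = 2L)
  )
}

slot_accepts <- function(slot, category) {
  if (slot == "functional") category %in% functional_categories()
  else slot == category
}

#' Plan a shuttle plasmid from a vector-type grammar
#'
#' Fills the template's slots with the chosen devices (slot order around
#' the circle is fixed by the adaptor classes, not by the order devices are
#' supplied), resolves each device's release enzyme, and rejects the plan
#' if any cyclically adjacent pair of faces fails [face_pairing()].
#'
#' @param vector_type A [vector_templates()] name.
#' @param devices Character vector of device ids (with `catalog`) or list
#'   of `gc_device` objects.
#' @param catalog Optional `gc_catalog` to resolve ids against.
#' @param custom For `knockout` plans: named list with `upstream` and
#'   `downstream` homology sequences (see [plan_knockout()]).
#' @return A `gc_plan`.
#' @export
plan_vector <- function(vector_type, devices, catalog = NULL, custom = NULL) {
  templates <- vector_templates()
  if (!vector_type %in% names(templates))
    stop(sprintf("unknown vector type: %s", vector_type), call. = FALSE)
  devices <- resolve_devices(devices, catalog)
  if (vector_type == "knockout") {
    for (side in c("upstream", "downstream"))
      if (is.null(custom[[side]]))
        stop(sprintf("knockout plan is missing the custom %s homology slot",
                     side), call. = FALSE)
    backbone <- pick_device(devices, "ecoli_origin_knockout")
    marker <- pick_device(devices, "antibiotic_marker")
    return(plan_knockout(custom$upstream, custom$downstream,
                         marker = marker, backbone = backbone))
  }
  template <- templates[[vector_type]]
  slots <- vector("list", length(template$slots))
  names(slots) <- template$slots
  used <- logical(length(devices))
  for (k in seq_along(template$slots)) {
    slot <- template$slots[k]
    hit <- which(!used & vapply(devices, function(d)
      slot_accepts(slot, d$category), logical(1)))
    if (length(hit) == 0L)
      stop(sprintf("missing device for slot %s", slot), call. = FALSE)
    if (length(hit) > 1L)
      stop(sprintf("more than one chosen device fits slot %s: %s", slot,
                   paste(vapply(devices[hit], `[[`, character(1), "id"),
                         collapse = ", ")), call. = FALSE)
    used[hit] <- TRUE
    d <- devices[[hit]]
    rep <- validate_device(d)
    if (!rep$valid)
      stop(sprintf("device %s is invalid: %s", d$id,
                   paste(rep$violations, collapse = "; ")), call. = FALSE)
    slots[[k]] <- list(slot = slot, kind = "device", device = d)
  }
  if (any(!used)) {
    extra <- vapply(devices[!used], function(d)
      sprintf("%s (%s)", d$id, d$category), character(1))
    stop(sprintf("chosen device(s) fit no slot of %s: %s", vector_type,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  new_plan(vector_type, slots)
}

resolve_devices <- function(devices, catalog) {
  if (inherits(devices, "gc_device")) devices <- list(devices)
  if (is.character(devices)) {
    if (is.null(catalog))
      stop("device ids require a catalog", call. = FALSE)
    devices <- lapply(devices, function(id) {
      d <- catalog$devices[[id]]
      if (is.null(d)) stop(sprintf("device %s not in catalog", id),
                           call. = FALSE)
      d
    })
  }
  devices
}

pick_device <- function(devices, category) {
  hit <- which(vapply(devices, function(d) d$category == category,
                      logical(1)))
  if (length(hit) != 1L)
    stop(sprintf("expected exactly one %s device, got %d", category,
                 length(hit)), call. = FALSE)
  devices[[hit]]
}

new_plan <- function(vector_type, slots) {
  slots <- unname(slots)
  # cyclic adjacency: every right face must pair with the next left face
  n <- length(slots)
  for (k in seq_len(n)) {
    a <- slot_faces(slots[[k]])
    b <- slot_faces(slots[[if (k == n) 1L else k + 1L]])
    if (!face_pairing(b$left, a$right))
      stop(sprintf(
        "adaptor incompatibility between slot %s (right %s) and slot %s (left %s)",
        slots[[k]]$slot, a$right$label, slots[[if (k == n) 1L else k + 1L]]$slot,
        b$left$label), call. = FALSE)
  }
  structure(list(vector_type = vector_type, slots = slots),
            class = "gc_plan")
}

slot_faces <- function(slot) {
  if (slot$kind == "device")
    list(left = slot$device$left_face, right = slot$device$right_face)
  else
    list(left = slot$left_face, right = slot$right_face)
}

slot_id <- function(slot) {
  if (slot$kind == "device") slot$device$id else slot$id
}

slot_enzyme <- function(slot) {
  if (slot$kind == "device") slot$device$release_enzyme else slot$enzyme
}

#' @export
print.gc_plan <- function(x, ...) {
  cat(sprintf("<assembly plan> %s, %d slot(s)\n", x$vector_type,
              length(x$slots)))
  for (s in x$slots) {
    f <- slot_faces(s)
    cat(sprintf("  %-22s %-8s %-18s %s | %s  (%s)\n", s$slot, s$kind,
                slot_id(s), f$left$label, f$right$label, slot_enzyme(s)))
  }
  invisible(x)
}

#' Plan a gene-knockout (suicide) vector
#'
#' Four-fragment circular plan: knockout E. coli origin backbone
#' (G5C5|C3G3) -> upstream homology (C3G3|GC tails) -> antibiotic marker
#' (GC|C2G) -> downstream homology (C2G|G5C5 tails). The homology arms are
#' custom PCR fragments; adaptor-tailed primers for both are emitted via
#' [design_tailed_primers()], and in silico the tailed amplicons are
#' digested with their release enzyme before assembly so that their ends
#' are standard 21-mers.
#'
#' @param upstream_homology,downstream_homology Homology arm sequences.
#' @param marker An `antibiotic_marker` device.
#' @param backbone An `ecoli_origin_knockout` device.
#' @param min_homology Minimum homology arm length in nt (default 100).
#' @param primer_length Target-specific primer length (default 20).
#' @return A `gc_plan` whose custom slots carry sequences, faces, release
#'   enzymes and tailed primer pairs.
#' @export
plan_knockout <- function(upstream_homology, downstream_homology, marker,
                          backbone, min_homology = 100L,
                          primer_length = 20L) {
  if (marker$category != "antibiotic_marker")
    stop(sprintf("marker device must be antibiotic_marker, got %s",
                 marker$category), call. = FALSE)
  if (backbone$category != "ecoli_origin_knockout")
    stop(sprintf("backbone device must be ecoli_origin_knockout, got %s",
                 backbone$category), call. = FALSE)
  arms <- list(upstream = seq_chars(upstream_homology),
               downstream = seq_chars(downstream_homology))
  for (side in names(arms))
    if (nchar(arms[[side]]) < min_homology)
      stop(sprintf("%s homology too short: %d nt < %d nt", side,
                   nchar(arms[[side]]), min_homology), call. = FALSE)
  face_labels <- list(upstream = c("C3G3-MfeI", "NheI-GC"),
                      downstream = c("C2G-AgeI", "XbaI-G5C5"))
  custom_slots <- lapply(names(arms), function(side) {
    seqc <- arms[[side]]
    enzyme <- choose_enzyme(seqc)
    lf <- adaptor_face(face_labels[[side]][1], enzyme)
    rf <- adaptor_face(face_labels[[side]][2], enzyme)
    npr <- min(primer_length, nchar(seqc))
    primers <- design_tailed_primers(
      substr(seqc, 1L, npr),
      rc_string(substr(seqc, nchar(seqc) - npr + 1L, nchar(seqc))),
      lf, rf, enzyme = enzyme)
    list(slot = paste0("custom_", side), kind = "custom",
         id = paste0(side, "_homology"), sequence = seqc,
         left_face = lf, right_face = rf, enzyme = enzyme$name,
         primers = primers)
  })
  slots <- list(
    list(slot = "ecoli_origin_knockout", kind = "device", device = backbone),
    custom_slots[[1]],
    list(slot = "antibiotic_marker", kind = "device", device = marker),
    custom_slots[[2]])
  new_plan("knockout", slots)
}

#' Design adaptor-tailed PCR primers for a device or homology arm
#'
#' The forward primer is the left flank string followed by the
#' target-specific forward primer; the reverse primer is the right flank
#' string (stored in its bottom-strand orientation, which is the strand the
#' reverse primer extends) followed by the target-specific reverse primer.
#' Both flanks carry the release site of the chosen enzyme.
#'
#' @param target_fwd,target_rev Target-specific primer sequences (non-empty).
#' @param left_face,right_face `gc_face` objects or adaptor labels.
#' @param enzyme Release enzyme for the tails; defaults to the left face's
#'   own release enzyme (the enzyme its flank is printed with).
#' @return A `gc_primer_pair`.
#' @export
design_tailed_primers <- function(target_fwd, target_rev, left_face,
                                  right_face, enzyme = NULL) {
  left_face <- as_face(left_face)
  right_face <- as_face(right_face)
  enzyme <- as_enzyme(if (is.null(enzyme)) left_face$enzyme else enzyme)
  target_fwd <- seq_chars(target_fwd)
  target_rev <- seq_chars(target_rev)
  lf <- adaptor_face(left_face$label, enzyme)
  rf <- adaptor_face(right_face$label, enzyme)
  structure(list(forward = paste0(lf$flank, target_fwd),
                 reverse = paste0(rf$flank, target_rev),
                 target_fwd = target_fwd, target_rev = target_rev,
                 left_face = lf, right_face = rf, enzyme = enzyme$name),
            class = "gc_primer_pair")
}

#' @export
print.gc_primer_pair <- function(x, ...) {
  cat(sprintf("<tailed primers> release %s\n  fwd (%d nt): %s\n  rev (%d nt): %s\n",
              x$enzyme, nchar(x$forward), x$forward, nchar(x$reverse),
              x$reverse))
  invisible(x)
}

#' Simulate the amplicon produced by a tailed primer pair
#'
#' @param primers A `gc_primer_pair`.
#' @param target Template region, beginning with the forward primer's
#'   annealing sequence and ending with the reverse complement of the
#'   reverse primer's.
#' @return Linear `gc_dna` amplicon: left flank + target + reverse
#'   complement of the right flank.
#' @export
simulate_amplicon <- function(primers, target) {
  target <- seq_chars(target)
  if (!startsWith(target, primers$target_fwd) ||
      !endsWith(target, rc_string(primers$target_rev)))
    stop("primers do not match the target termini", call. = FALSE)
  dna(paste0(primers$left_face$flank, target,
             rc_string(primers$right_face$flank)))
}

# --- fragments -------------------------------------------------------------

adaptor_end <- function(face, enzyme) {
  list(kind = "adaptor", enzyme = enzyme, class = face$class,
       overlap = 21L)
}

custom_end <- function(tail) {
  list(kind = "custom", enzyme = "PCR", class = NA_character_,
       overlap = nchar(tail))
}

new_fragment <- function(id, seqc, left_end, right_end) {
  structure(list(id = id, seq = seqc, left_end = left_end,
                 right_end = right_end),
            class = "gc_fragment")
}

#' @export
print.gc_fragment <- function(x, ...) {
  endlab <- function(e) if (e$kind == "adaptor")
    sprintf("%s/%s", e$class, e$enzyme) else sprintf("custom/%dnt", e$overlap)
  cat(sprintf("<fragment> %s, %d nt [%s ... %s]\n", x$id, nchar(x$seq),
              endlab(x$left_end), endlab(x$right_end)))
  invisible(x)
}

# release one custom (tailed amplicon) slot
release_custom <- function(slot) {
  amplicon <- dna(paste0(slot$left_face$flank, slot$sequence,
                         rc_string(slot$right_face$flank)))
  frags <- blunt_digest(amplicon, slot$enzyme)
  mid <- Filter(function(f) !is.na(f$left_enzyme) && !is.na(f$right_enzyme),
                frags)
  if (length(mid) != 1L)
    stop(sprintf("custom fragment %s: digestion did not yield a unique tailed fragment",
                 slot$id), call. = FALSE)
  new_fragment(slot$id, mid[[1]]$seq,
               adaptor_end(slot$left_face, slot$enzyme),
               adaptor_end(slot$right_face, slot$enzyme))
}

#' Release the planned fragments from their donor plasmids
#'
#' Device slots are digested out of their donors with the per-device
#' release enzyme; backbone fragments are discarded (stray sites in the
#' donor backbone are tolerated as long as the device payload is released
#' intact and unique). Custom slots are simulated as tailed amplicons and
#' digested likewise.
#'
#' @param plan A `gc_plan`.
#' @param donors List of `gc_donor` or a `gc_catalog`.
#' @return List of `gc_fragment`, in slot order.
#' @export
release_fragments <- function(plan, donors) {
  lapply(plan$slots, function(slot) {
    if (slot$kind == "custom") return(release_custom(slot))
    d <- slot$device
    donor <- donor_for_device(donors, d$id)
    frags <- blunt_digest(donor$sequence, d$release_enzyme)
    hit <- which(vapply(frags, function(f)
      grepl(d$payload$bases, f$seq, fixed = TRUE), logical(1)))
    if (length(hit) != 1L) {
      sites <- scan_sites(donor$sequence, d$release_enzyme)
      stop(sprintf(
        "donor %s: %s digestion at position(s) %s does not release device %s intact",
        donor$id, d$release_enzyme, paste(sites, collapse = ","), d$id),
        call. = FALSE)
    }
    new_fragment(d$id, frags[[hit]]$seq,
                 adaptor_end(d$left_face, d$release_enzyme),
                 adaptor_end(d$right_face, d$release_enzyme))
  })
}

oriented_seq <- function(frag, flip) {
  if (flip) rc_string(frag$seq) else frag$seq
}

oriented_ends <- function(frag, flip) {
  if (flip) list(left = frag$right_end, right = frag$left_end)
  else list(left = frag$left_end, right = frag$right_end)
}

# overlap alignment between the tail of A and the head of B; returns NULL
# or list(k, mismatches = integer positions, normalized)
align_overlap <- function(a, b, allowed, min_overlap, max_overlap = 30L) {
  kmax <- min(max_overlap, nchar(a), nchar(b))
  if (kmax < min_overlap) return(NULL)
  for (k in kmax:min_overlap) {
    sa <- strsplit(substr(a, nchar(a) - k + 1L, nchar(a)), "")[[1]]
    sb <- strsplit(substr(b, 1L, k), "")[[1]]
    mm <- which(sa != sb)
    if (length(mm) <= allowed) {
      norm <- sb
      for (p in mm) {
        pair <- sort(c(sa[p], sb[p]))
        norm[p] <- if (identical(pair, c("A", "G"))) "A"
                   else if (identical(pair, c("C", "T"))) "T"
                   else sa[p]
      }
      return(list(k = k, mismatches = mm,
                  normalized = paste(norm, collapse = "")))
    }
  }
  NULL
}

#' Build the junction graph over released fragments
#'
#' Draws a directed edge from the right end of one oriented fragment to
#' the left end of another when their terminal sequences align with at
#' most `max_mismatch` mismatches over at least `min_overlap` positions.
#' Both orientations of every fragment are considered, so fragments
#' supplied in flipped orientation are joined through their reverse
#' complement. Adaptor-to-adaptor joints tolerate `max_mismatch`
#' (the EcoRV/ZraI half-site G/T heteroduplex); joints involving a custom
#' (free-form) end require an exact match.
#'
#' @param fragments List of `gc_fragment`.
#' @param max_mismatch Maximum mismatches in an adaptor-adaptor overlap.
#' @param min_overlap Minimum aligned positions.
#' @return A `gc_junction_graph`.
#' @export
find_junctions <- function(fragments, max_mismatch = 1L, min_overlap = 15L) {
  n <- length(fragments)
  if (n < 2L) stop("need at least two fragments", call. = FALSE)
  edges <- list()
  for (i in seq_len(n)) for (oi in c(FALSE, TRUE)) {
    a <- oriented_seq(fragments[[i]], oi)
    ea <- oriented_ends(fragments[[i]], oi)$right
    for (j in seq_len(n)) for (oj in c(FALSE, TRUE)) {
      if (i == j) next
      b <- oriented_seq(fragments[[j]], oj)
      eb <- oriented_ends(fragments[[j]], oj)$left
      both_adaptor <- ea$kind == "adaptor" && eb$kind == "adaptor"
      allowed <- if (both_adaptor) max_mismatch else 0L
      hit <- align_overlap(a, b, allowed, min_overlap)
      if (is.null(hit)) next
      class <- if (both_adaptor && identical(ea$class, eb$class)) ea$class
               else "custom"
      edges[[length(edges) + 1L]] <- list(
        from = i, from_flip = oi, to = j, to_flip = oj,
        upstream = fragments[[i]]$id, downstream = fragments[[j]]$id,
        class = class, overlap = hit$k,
        mismatch_count = length(hit$mismatches),
        mismatch_positions = hit$mismatches,
        normalized = hit$normalized,
        wallace_tm_C = wallace_tm(hit$normalized))
    }
  }
  structure(list(fragments = fragments, edges = edges,
                 max_mismatch = max_mismatch, min_overlap = min_overlap),
            class = "gc_junction_graph")
}

#' @export
print.gc_junction_graph <- function(x, ...) {
  cat(sprintf("<junction graph> %d fragment(s), %d candidate junction(s)\n",
              length(x$fragments), length(x$edges)))
  for (e in x$edges)
    cat(sprintf("  %s%s -> %s%s  %s overlap %d, %d mismatch(es), Tm %d C\n",
                e$upstream, if (e$from_flip) "(rc)" else "",
                e$downstream, if (e$to_flip) "(rc)" else "",
                e$class, e$overlap, e$mismatch_count, e$wallace_tm_C))
  invisible(x)
}

# all Hamiltonian cycles through the junction graph, anchored at fragment 1
# in forward orientation (strand choice; the reverse-complement traversal of
# a circle is the same molecule)
hamiltonian_cycles <- function(graph) {
  n <- length(graph$fragments)
  edge_from <- function(i, oi) Filter(function(e)
    e$from == i && identical(e$from_flip, oi), graph$edges)
  cycles <- list()
  path <- list(list(i = 1L, flip = FALSE))
  visit <- function(path, used) {
    last <- path[[length(path)]]
    for (e in edge_from(last$i, last$flip)) {
      if (e$to == 1L && !e$to_flip && length(path) == n) {
        cycles[[length(cycles) + 1L]] <<- list(path = path,
                                               closing = e)
      } else if (!used[e$to] && length(path) < n) {
        visit(c(path, list(list(i = e$to, flip = e$to_flip, via = e))),
              `[<-`(used, e$to, TRUE))
      }
    }
  }
  visit(path, `[<-`(logical(n), 1L, TRUE))
  cycles
}

#' Assemble the unique circular plasmid from a junction graph
#'
#' Succeeds when the junction graph admits exactly one circular order over
#' all fragments. The output sequence writes each junction overlap once,
#' with any EcoRV/ZraI half-site mismatch normalized to the EcoRV-dialect
#' base (ATC/GAT), so the assembled sequence is independent of which
#' enzyme released each fragment. Device part annotations are lifted onto
#' the plasmid. The sequence is reported as the lexicographically minimal
#' rotation of the strand on which the first-listed fragment lies forward.
#'
#' @param graph A `gc_junction_graph` (or list of fragments, in which case
#'   [find_junctions()] is run with defaults).
#' @param id Identifier for the assembled plasmid.
#' @param devices Optional list of `gc_device` used to lift part
#'   annotations (matched to fragments by id).
#' @return A `gc_plasmid`: circular sequence, junction table, features,
#'   provenance.
#' @export
assemble_circle <- function(graph, id = "assembly", devices = NULL) {
  if (!inherits(graph, "gc_junction_graph")) graph <- find_junctions(graph)
  frags <- graph$fragments
  n <- length(frags)
  cycles <- hamiltonian_cycles(graph)
  if (length(cycles) == 0L) {
    unpaired <- character(0)
    for (i in seq_len(n)) {
      if (!any(vapply(graph$edges, function(e)
        e$from == i && !e$from_flip, logical(1))))
        unpaired <- c(unpaired, sprintf("%s right (%s)", frags[[i]]$id,
                                        frags[[i]]$right_end$class))
      if (!any(vapply(graph$edges, function(e)
        e$to == i && !e$to_flip, logical(1))))
        unpaired <- c(unpaired, sprintf("%s left (%s)", frags[[i]]$id,
                                        frags[[i]]$left_end$class))
    }
    stop(sprintf("open assembly: unpaired end(s): %s",
                 if (length(unpaired)) paste(unpaired, collapse = "; ")
                 else "no closing junction"), call. = FALSE)
  }
  if (length(cycles) > 1L) {
    orders <- vapply(cycles, function(cy)
      paste(vapply(cy$path, function(nd) frags[[nd$i]]$id, character(1)),
            collapse = " -> "), character(1))
    stop(sprintf("ambiguous assembly: %d distinct circular orders:\n  %s",
                 length(cycles), paste(orders, collapse = "\n  ")),
         call. = FALSE)
  }
  cy <- cycles[[1]]
  nodes <- cy$path
  edges_in <- c(list(cy$closing), lapply(nodes[-1], `[[`, "via"))
  # edges_in[[k]] is the junction written at the start of segment k
  seqs <- vapply(seq_len(n), function(k) {
    nd <- nodes[[k]]
    e_in <- edges_in[[k]]
    e_out <- if (k < n) edges_in[[k + 1L]] else edges_in[[1L]]
    s <- oriented_seq(frags[[nd$i]], nd$flip)
    paste0(e_in$normalized,
           substr(s, e_in$overlap + 1L, nchar(s) - e_out$overlap))
  }, character(1))
  offsets <- cumsum(c(0L, nchar(seqs)))[seq_len(n)]
  circle <- paste(seqs, collapse = "")
  L <- nchar(circle)

  junctions <- do.call(rbind, lapply(seq_len(n), function(k) {
    e <- edges_in[[k]]
    data.frame(upstream = e$upstream, downstream = e$downstream,
               class = e$class, overlap = e$overlap,
               mismatch_count = e$mismatch_count,
               mismatch_positions = paste(e$mismatch_positions,
                                          collapse = ","),
               wallace_tm_C = e$wallace_tm_C,
               start = offsets[k] + 1L, end = offsets[k] + e$overlap,
               stringsAsFactors = FALSE)
  }))

  features <- lift_part_features(nodes, edges_in, offsets, frags, devices, L)

  rot <- least_rotation_index(circle) - 1L   # 0-based shift
  circle <- rotate_string(circle, rot)
  shift <- function(pos) ((pos - 1L - rot) %% L) + 1L
  junctions$start <- shift(junctions$start)
  junctions$end <- junctions$start + junctions$overlap - 1L
  if (nrow(features)) {
    w <- features$end - features$start
    features$start <- shift(features$start)
    features$end <- features$start + w
  }
  junctions <- junctions[order(junctions$start), , drop = FALSE]
  rownames(junctions) <- NULL

  structure(list(id = id, sequence = dna(circle, "circular"),
                 junctions = junctions, features = features,
                 provenance = list(
                   fragment_order = vapply(nodes, function(nd)
                     frags[[nd$i]]$id, character(1)),
                   flipped = vapply(nodes, `[[`, logical(1), "flip"))),
            class = "gc_plasmid")
}

lift_part_features <- function(nodes, edges_in, offsets, frags, devices, L) {
  if (is.null(devices)) return(empty_features())
  names(devices) <- vapply(devices, `[[`, character(1), "id")
  rows <- list()
  for (k in seq_along(nodes)) {
    nd <- nodes[[k]]
    frag <- frags[[nd$i]]
    d <- devices[[frag$id]]
    if (is.null(d) || !nrow(d$parts)) next
    flen <- nchar(frag$seq)
    # payload sits inside 27-nt remnants (21-mer + 6-nt secondary site)
    for (r in seq_len(nrow(d$parts))) {
      fs <- 27L + d$parts$start[r]
      fe <- 27L + d$parts$end[r]
      strand <- d$parts$strand[r]
      if (nd$flip) {
        tmp <- flen - fe + 1L
        fe <- flen - fs + 1L
        fs <- tmp
        strand <- if (strand == "+") "-" else "+"
      }
      start <- ((offsets[k] + fs - 1L) %% L) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        key = "misc_feature", start = start, end = start + (fe - fs),
        strand = strand, label = d$parts$part_id[r],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_features()
}

#' @export
print.gc_plasmid <- function(x, ...) {
  cat(sprintf("<assembled plasmid> %s, %d bp circular, %d junction(s), %d feature(s)\n",
              x$id, nchar(x$sequence$bases), nrow(x$junctions),
              nrow(x$features)))
  if (nrow(x$junctions))
    print(x$junctions[, c("upstream", "downstream", "class", "overlap",
                          "mismatch_count", "wallace_tm_C")])
  invisible(x)
}

# index (1-based) of the lexicographically minimal rotation
least_rotation_index <- function(s) {
  n <- nchar(s)
  ch <- strsplit(paste0(s, s), "")[[1]]
  cand <- which(ch[seq_len(n)] == min(ch[seq_len(n)]))
  k <- 1L
  while (length(cand) > 1L && k < n) {
    nxt <- ch[cand + k]
    cand <- cand[nxt == min(nxt)]
    k <- k + 1L
  }
  cand[1L]
}

rotate_string <- function(s, shift) {
  n <- nchar(s)
  shift <- shift %% n
  if (shift == 0L) return(s)
  paste0(substr(s, shift + 1L, n), substr(s, 1L, shift))
}

#' Plan, release and assemble in one call
#'
#' @param plan A `gc_plan`.
#' @param donors List of `gc_donor` or a `gc_catalog`.
#' @param id Plasmid identifier.
#' @param max_mismatch,min_overlap Passed to [find_junctions()].
#' @return A `gc_plasmid`.
#' @export
assemble <- function(plan, donors, id = "assembly", max_mismatch = 1L,
                     min_overlap = 15L) {
  frags <- release_fragments(plan, donors)
  graph <- find_junctions(frags, max_mismatch = max_mismatch,
                          min_overlap = min_overlap)
  devices <- lapply(Filter(function(s) s$kind == "device", plan$slots),
                    `[[`, "device")
  assemble_circle(graph, id = id, devices = devices)
}

#' Replace the ccdB cloning cassette of a vector with an insert
#'
#' The vector must contain the replaceable cloning cassette: a ccdB gene
#' bracketed by two SwaI sites with the two published 25-nt adaptors
#' outside them. Opening with SwaI drops the toxic fragment; a PCR insert
#' carrying the two 25-nt tails (left tail verbatim at its start, reverse
#' complement of the right tail at its end) joins the opened backbone
#' through two exact 25-nt overlaps.
#'
#' @param vector A `gc_plasmid`, `gc_record` or circular `gc_dna`.
#' @param insert Linear insert sequence with both tails attached.
#' @param tails The two 25-nt overlap adaptors (default the published
#'   pair, [cassette_adaptors()]).
#' @param parts Optional parts database used to re-annotate the product.
#' @param id Identifier for the product.
#' @return A `gc_plasmid` with two overlap-25 junctions; the removed
#'   cassette fragment is attached as `$removed`.
#' @export
insert_into_cloning_cassette <- function(vector, insert,
                                         tails = cassette_adaptors(),
                                         parts = NULL, id = "insertion") {
  vec <- if (inherits(vector, "gc_plasmid") || inherits(vector, "gc_record"))
    vector$sequence else vector
  if (!inherits(vec, "gc_dna") || vec$topology != "circular")
    stop("vector must be a circular sequence", call. = FALSE)
  sites <- scan_sites(vec, "SwaI")
  if (length(sites) < 2L)
    stop("no SwaI cloning cassette in the vector", call. = FALSE)
  if (length(sites) > 2L)
    stop(sprintf("more than one SwaI cassette candidate (%d sites)",
                 length(sites)), call. = FALSE)
  frags <- blunt_digest(vec, "SwaI")
  insert <- seq_chars(insert)
  tl <- seq_chars(tails[["left"]])
  tr_rc <- rc_string(seq_chars(tails[["right"]]))
  nl <- nchar(tl); nr <- nchar(tr_rc)
  if (nchar(insert) <= nl + nr)
    stop("insert shorter than its two tails", call. = FALSE)
  compatible <- vapply(frags, function(f) {
    endsWith(f$seq, tl) && startsWith(f$seq, tr_rc) &&
      startsWith(insert, tl) && endsWith(insert, tr_rc)
  }, logical(1))
  if (sum(compatible) != 1L)
    stop("tail mismatch: insert termini do not match the opened cassette",
         call. = FALSE)
  backbone <- frags[[which(compatible)]]$seq
  removed <- frags[[which(!compatible)]]$seq
  circle <- paste0(backbone, substr(insert, nl + 1L, nchar(insert) - nr))
  L <- nchar(circle)
  lb <- nchar(backbone)
  junctions <- data.frame(
    upstream = c("backbone", "insert"), downstream = c("insert", "backbone"),
    class = "custom", overlap = c(nl, nr), mismatch_count = 0L,
    mismatch_positions = "", wallace_tm_C = c(wallace_tm(tl),
                                              wallace_tm(tr_rc)),
    start = c(lb - nl + 1L, ((lb + nchar(insert) - nl - nr) %% L) + 1L),
    stringsAsFactors = FALSE)
  junctions$end <- junctions$start + junctions$overlap - 1L
  rot <- least_rotation_index(circle) - 1L
  circle <- rotate_string(circle, rot)
  junctions$start <- ((junctions$start - 1L - rot) %% L) + 1L
  junctions$end <- junctions$start + junctions$overlap - 1L
  features <- if (!is.null(parts))
    annotate_with_parts(dna(circle, "circular"), parts)
  else empty_features()
  out <- structure(list(id = id, sequence = dna(circle, "circular"),
                        junctions = junctions, features = features,
                        provenance = list(fragment_order =
                                            c("backbone", "insert")),
                        removed = removed),
                   class = "gc_plasmid")
  out
}
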