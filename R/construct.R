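#' Declare an in-silico reporter-UTR construct
#'
#' A construct is built by replaying an ordered list of edits over named
#' source parts, mirroring how mutant reporter UTRs are assembled in the lab:
#' truncations, insertions at a position (position 0 inserts before base 1),
#' fusions of two parts and deletions. Coordinates in every edit are 1-based
#' inclusive and are interpreted against the sequence *as it stands when the
#' edit is applied*.
#'
#' The edits are built with [edit_take()], [edit_insert_at()], [edit_fuse()]
#' and [edit_delete()]. Replaying a spec is deterministic, and [apply_edits()]
#' records a provenance log (one row per edit with before/after lengths) so a
#' construct can be audited and reproduced byte-for-byte.
#'
#' @param name construct name.
#' @param parts a named list of [region()] objects (or plain sequences) the
#'   edits may reference by name.
#' @param edits an ordered list of edit operations.
#' @param base name of the part the edit chain starts from (default the
#'   first part). Ignored when the first edit is a fuse.
#' @return an object of class `"construct_spec"`.
#' @examples
#' parts <- list(utr = "ATATATATAT", donor = "GGCC")
#' spec <- construct_spec("demo", parts,
#'                        list(edit_insert_at(0, "donor")))
#' apply_edits(spec)$seq  # "GGCCATATATATAT"
#' @export
construct_spec <- function(name, parts, edits, base = names(parts)[1]) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(parts), length(parts) >= 1L,
            !is.null(names(parts)), all(nzchar(names(parts))),
            is.list(edits))
  parts <- lapply(parts, as_seq_string)
  if (!base %in% names(parts))
    stop("construct '", name, "': base part '", base, "' not among parts")
  for (e in edits)
    if (!inherits(e, "construct_edit"))
      stop("construct '", name, "': edits must be built with edit_*()")
  structure(list(name = name, parts = parts, edits = edits, base = base),
            class = "construct_spec")
}

#' @rdname construct_spec
#' @param start,end 1-based inclusive coordinates on the current sequence.
#' @export
edit_take <- function(start, end) {
  structure(list(op = "take", start = as.integer(start),
                 end = as.integer(end)),
            class = "construct_edit")
}

#' @rdname construct_spec
#' @param position insertion point: the donor goes between positions
#'   `position` and `position + 1` of the current sequence; 0 inserts before
#'   base 1, the current length appends.
#' @param donor a part name, or a sequence/[region()] inserted literally.
#' @param donor_start,donor_end optional 1-based inclusive coordinates taking
#'   only a fragment of the donor (default: the whole donor).
#' @export
edit_insert_at <- function(position, donor, donor_start = NULL,
                           donor_end = NULL) {
  structure(list(op = "insert_at", position = as.integer(position),
                 donor = donor,
                 donor_start = if (!is.null(donor_start)) as.integer(donor_start),
                 donor_end = if (!is.null(donor_end)) as.integer(donor_end)),
            class = "construct_edit")
}

#' @rdname construct_spec
#' @param front,back part names (or literal sequences) concatenated
#'   front-then-back; the result replaces the current sequence.
#' @export
edit_fuse <- function(front, back) {
  structure(list(op = "fuse", front = front, back = back),
            class = "construct_edit")
}

#' @rdname construct_spec
#' @export
edit_delete <- function(start, end) {
  structure(list(op = "delete", start = as.integer(start),
                 end = as.integer(end)),
            class = "construct_edit")
}

resolve_donor <- function(x, parts, name) {
  if (is.character(x) && length(x) == 1L && x %in% names(parts))
    return(parts[[x]])
  as_seq_string(x)
}

#' Build a construct by replaying its edit program
#'
#' Applies the edits of a [construct_spec()] in order, starting from the
#' base part. Each edit re-evaluates its coordinates against the current
#' sequence, so an insertion changes the addresses of everything downstream
#' of it for later edits. Out-of-bounds coordinates are fatal, naming the
#' edit.
#'
#' @param spec a [construct_spec()].
#' @return a [region()] spanning the finished construct, with attribute
#'   `"provenance_log"`: a data frame with one row per edit (`step`, `op`,
#'   `detail`, `len_before`, `len_after`).
#' @export
apply_edits <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  cur <- spec$parts[[spec$base]]
  log <- data.frame(step = integer(), op = character(), detail = character(),
                    len_before = integer(), len_after = integer())
  for (k in seq_along(spec$edits)) {
    e <- spec$edits[[k]]
    before <- nchar(cur)
    detail <- ""
    if (e$op == "take") {
      if (e$start < 1L || e$end > nchar(cur) || e$start > e$end)
        stop("construct '", spec$name, "', edit ", k, " (take): [",
             e$start, ", ", e$end, "] out of bounds for length ", nchar(cur))
      cur <- substr(cur, e$start, e$end)
      detail <- paste0("[", e$start, "-", e$end, "]")
    } else if (e$op == "insert_at") {
      donor <- resolve_donor(e$donor, spec$parts, spec$name)
      ds <- if (is.null(e$donor_start)) 1L else e$donor_start
      de <- if (is.null(e$donor_end)) nchar(donor) else e$donor_end
      if (ds < 1L || de > nchar(donor) || ds > de)
        stop("construct '", spec$name, "', edit ", k,
             " (insert_at): donor fragment [", ds, ", ", de,
             "] out of bounds for donor length ", nchar(donor))
      donor <- substr(donor, ds, de)
      if (e$position < 0L || e$position > nchar(cur))
        stop("construct '", spec$name, "', edit ", k,
             " (insert_at): position ", e$position,
             " outside [0, ", nchar(cur), "]")
      cur <- paste0(substr(cur, 1L, e$position), donor,
                    substr(cur, e$position + 1L, nchar(cur)))
      detail <- paste0(nchar(donor), " nt after position ", e$position)
    } else if (e$op == "fuse") {
      front <- resolve_donor(e$front, spec$parts, spec$name)
      back <- resolve_donor(e$back, spec$parts, spec$name)
      cur <- paste0(front, back)
      detail <- paste0(nchar(front), " + ", nchar(back), " nt")
    } else if (e$op == "delete") {
      if (e$start < 1L || e$end > nchar(cur) || e$start > e$end)
        stop("construct '", spec$name, "', edit ", k, " (delete): [",
             e$start, ", ", e$end, "] out of bounds for length ", nchar(cur))
      cur <- paste0(substr(cur, 1L, e$start - 1L),
                    substr(cur, e$end + 1L, nchar(cur)))
      detail <- paste0("[", e$start, "-", e$end, "]")
    } else {
      stop("construct '", spec$name, "': unknown edit op '", e$op, "'")
    }
    log[nrow(log) + 1L, ] <- list(k, e$op, detail, before, nchar(cur))
  }
  out <- region(spec$name, "custom", 1L, nchar(cur), cur)
  attr(out, "provenance_log") <- log
  out
}

#' Delete externally supplied motif intervals from a region
#'
#' Convenience for building deletion mutants (e.g. removing predicted AREs):
#' turns a hit table — from [scan_are()] or an external BED-like TSV with
#' `start`/`end` columns, 1-based inclusive — into `delete` edits applied
#' right-to-left so earlier coordinates stay valid.
#'
#' @param region a [region()] or plain sequence.
#' @param hits a data frame with `start` and `end` columns.
#' @param name name for the resulting construct.
#' @return a [region()] with provenance, as from [apply_edits()].
#' @export
delete_intervals <- function(region, hits, name = "deletion_mutant") {
  stopifnot(all(c("start", "end") %in% names(hits)))
  hits <- hits[order(hits$start, decreasing = TRUE), , drop = FALSE]
  edits <- lapply(seq_len(nrow(hits)), function(i)
    edit_delete(hits$start[i], hits$end[i]))
  apply_edits(construct_spec(name, list(source = as_seq_string(region)),
                             edits))
}
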