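#' DeleteDoc redundancy elimination
#'
#' Reduces each record to its single source note and discards the rest, the
#' drastic way of guaranteeing a redundancy-free corpus. The vocabulary is
#' left unchanged so topic-word matrices stay comparable across methods.
#'
#' @param corpus A `record_corpus`.
#' @param annotation A `redundancy_annotation` designating each record's
#'   source note.
#' @return A `record_corpus` with exactly one note per record.
#' @export
delete_doc_transform <- function(corpus, annotation) {
  records <- lapply(corpus$records, function(rec) {
    src <- annotation$records[[rec$record_id]]$source_note
    if (is.null(src)) stop(sprintf("record '%s' has no designated source",
                                   rec$record_id))
    list(record_id = rec$record_id, notes = rec$notes[src])
  })
  new_record_corpus(records, corpus$vocab)
}

#' DeleteWord redundancy elimination
#'
#' Keeps every note but strips the tokens flagged as copied from the
#' non-source notes, preserving the original order of the remaining tokens.
#' Notes left empty are dropped (zero-length documents are degenerate for
#' LDA) with a warning naming them.
#'
#' @param corpus A `record_corpus`.
#' @param annotation A `redundancy_annotation` covering the corpus.
#' @return A `record_corpus` with copied tokens removed.
#' @export
delete_word_transform <- function(corpus, annotation) {
  dropped <- character(0)
  records <- lapply(corpus$records, function(rec) {
    arec <- annotation$records[[rec$record_id]]
    if (is.null(arec)) stop(sprintf("record '%s' not annotated", rec$record_id))
    notes <- list()
    for (nid in names(rec$notes)) {
      note <- rec$notes[[nid]]
      if (nid == arec$source_note) {
        notes[[nid]] <- note
        next
      }
      keep <- !arec$notes[[nid]]$copied
      if (!any(keep)) {
        dropped <<- c(dropped, paste(rec$record_id, nid, sep = "/"))
        next
      }
      notes[[nid]] <- new_note(
        nid, rec$record_id, note$raw_text, note$tokens[keep],
        if (!is.null(note$spans)) note$spans[keep, , drop = FALSE] else NULL)
    }
    list(record_id = rec$record_id, notes = notes)
  })
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d fully-copied note(s): %s", length(dropped),
                    paste(head(dropped, 5L), collapse = ", ")))
  }
  new_record_corpus(records, corpus$vocab)
}
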