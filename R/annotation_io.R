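#' Write a redundancy annotation as JSON lines
#'
#' One object per note with `record_id`, `note_id`, `source_note`, `copied`
#' (0/1 list) and `source_pos` (1-based token position in the source note,
#' -1 where not copied).
#'
#' @param annotation A `redundancy_annotation`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotation_jsonl <- function(annotation, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (rid in names(annotation$records)) {
    rec <- annotation$records[[rid]]
    for (nid in names(rec$notes)) {
      a <- rec$notes[[nid]]
      sp <- a$source_pos
      sp[is.na(sp)] <- -1L
      obj <- list(record_id = rid, note_id = nid,
                  source_note = rec$source_note,
                  copied = as.integer(a$copied), source_pos = as.integer(sp))
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a redundancy annotation written by [write_annotation_jsonl()]
#'
#' @param path Input file path.
#' @return A `redundancy_annotation`.
#' @export
read_annotation_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- list()
  for (ln in lines) {
    o <- jsonlite::fromJSON(ln)
    rid <- as.character(o$record_id)
    nid <- as.character(o$note_id)
    sp <- as.integer(unlist(o$source_pos))
    sp[sp < 0L] <- NA_integer_
    copied <- as.logical(as.integer(unlist(o$copied)))
    if (length(copied) == 0L) copied <- logical(0)
    if (is.null(records[[rid]])) {
      records[[rid]] <- list(source_note = as.character(o$source_note),
                             notes = list())
    }
    records[[rid]]$notes[[nid]] <- list(copied = copied, source_pos = sp)
  }
  structure(list(records = records, params = list()),
            class = "redundancy_annotation")
}
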