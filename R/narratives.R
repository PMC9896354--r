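#' Read narratives from JSON Lines
#'
#' One JSON object per line with keys `id`, `subject_id`, `language`,
#' `text`.  `id` must be unique within the file; `text` may be empty
#' (downstream scores then default to zero).
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return A data.frame with character columns `id`, `subject_id`,
#'   `language`, `text`, one row per narrative.
#' @seealso [write_narratives()]
#' @export
read_narratives <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), subject_id = character(),
                      language = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("malformed JSON on line ", i,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    need <- c("id", "subject_id", "language", "text")
    miss <- setdiff(need, names(obj))
    if (length(miss) > 0L) {
      stop("line ", i, ": missing field(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    data.frame(id = as.character(obj$id),
               subject_id = as.character(obj$subject_id),
               language = as.character(obj$language),
               text = as.character(obj$text), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0L) {
    stop("duplicate narrative id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write narratives to JSON Lines
#'
#' @param narratives Data.frame with columns `id`, `subject_id`,
#'   `language`, `text`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_narratives <- function(narratives, path) {
  stopifnot(all(c("id", "subject_id", "language", "text") %in%
                  names(narratives)))
  lines <- vapply(seq_len(nrow(narratives)), function(i) {
    jsonlite::toJSON(list(id = narratives$id[i],
                          subject_id = narratives$subject_id[i],
                          language = narratives$language[i],
                          text = narratives$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
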