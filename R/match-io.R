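# Round-tripping of match sets through a delimited table and JSON, and
# parsing of edit-command files.

#' Tabular view of a match set
#'
#' @param matches a `match_set`.
#' @param model_a,model_b the matched models (for display names).
#' @return data.frame with columns class, id_A, name_A, id_B, name_B, source,
#'   confidence, conflicts (";"-joined kinds).
#' @export
as_match_table <- function(matches, model_a, model_b) {
  rows <- lapply(matches$entries, function(e) {
    data.frame(class = e$class, id_A = e$id_a,
               name_A = model_element(model_a, e$class, e$id_a)$name,
               id_B = e$id_b,
               name_B = model_element(model_b, e$class, e$id_b)$name,
               source = e$source, confidence = e$confidence,
               conflicts = paste(e$conflicts$kind, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(class = character(0), id_A = character(0),
                      name_A = character(0), id_B = character(0),
                      name_B = character(0), source = character(0),
                      confidence = character(0), conflicts = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a match set as a delimited table
#' @inheritParams as_match_table
#' @param path output path (tab-separated).
#' @export
write_match_table <- function(matches, model_a, model_b, path) {
  utils::write.table(as_match_table(matches, model_a, model_b), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rebuild a match set from a delimited table
#'
#' Entries read from the table are re-attached to the two models; unmatched
#' lists are re-derived from the models' element inventories.
#' @param path path written by [write_match_table()].
#' @param model_a,model_b the matched models.
#' @export
read_match_table <- function(path, model_a, model_b) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  entries <- lapply(seq_len(nrow(df)), function(k) {
    kinds <- strsplit(df$conflicts[k], ";", fixed = TRUE)[[1]]
    kinds <- kinds[nzchar(kinds)]
    conf <- if (length(kinds) > 0) {
      data.frame(kind = kinds, detail = "", stringsAsFactors = FALSE)
    } else {
      NULL
    }
    .match_entry(df$class[k], df$id_A[k], df$id_B[k], df$source[k],
                 df$confidence[k], conf)
  })
  .new_match_set(model_a, model_b, entries)
}

#' Serialize a match set as JSON
#' @param matches a `match_set`; @param path optional file path.
#' @export
match_set_json <- function(matches, path = NULL) {
  obj <- list(
    model_a = matches$model_a_id, model_b = matches$model_b_id,
    entries = lapply(matches$entries, function(e) {
      list(class = e$class, id_a = e$id_a, id_b = e$id_b, source = e$source,
           confidence = e$confidence, conflicts = e$conflicts)
    }),
    unmatched_a = matches$unmatched_a, unmatched_b = matches$unmatched_b,
    candidate_conflicts = matches$candidate_conflicts)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Read edit commands from a JSON file
#'
#' The file holds a JSON list of edit objects as accepted by [apply_edits()].
#' @param path path to the JSON file.
#' @export
read_edit_commands <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
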