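# Coded species x character matrix with a keyword index over remarks.
#
# The matrix stores the full descriptions (cells are typed character
# values) plus an inverted index token -> species built from all remark
# fields. Rare characters that live only in remarks ("wing spot", "large
# fork") are therefore retrievable by keyword even though they are not
# coded columns.

#' Assemble descriptions into a coded matrix
#'
#' @param descriptions List of `megakey_description` objects, individually
#'   valid. Row order follows input order.
#' @return A `megakey_matrix`.
#' @export
build_matrix <- function(descriptions) {
  stopifnot(is.list(descriptions))
  if (length(descriptions)) {
    ok <- vapply(descriptions, inherits, TRUE, "megakey_description")
    if (!all(ok)) {
      mk_abort("all elements must be megakey_description objects",
               "megakey_validation_error")
    }
  }
  names_ <- unname(vapply(descriptions, `[[`, "", "taxon_name"))
  if (anyDuplicated(names_)) {
    dup <- names_[duplicated(names_)][1]
    mk_abort(sprintf("duplicate taxon name '%s'", dup), "megakey_build_error")
  }
  names(descriptions) <- names_
  structure(list(species = names_,
                 descriptions = descriptions,
                 remarks_index = build_remarks_index(descriptions)),
            class = "megakey_matrix")
}

# lowercase, strip punctuation, split on whitespace
tokenize_remarks <- function(text) {
  t <- tolower(text)
  t <- gsub("[^a-z0-9]+", " ", t)
  toks <- strsplit(trimws(t), "[[:space:]]+")[[1]]
  unique(toks[nzchar(toks)])
}

build_remarks_index <- function(descriptions) {
  idx <- list()
  for (d in descriptions) {
    text <- paste(c(d$general_remarks, unname(d$character_remarks)),
                  collapse = " ")
    for (tok in tokenize_remarks(text)) {
      idx[[tok]] <- union(idx[[tok]], d$taxon_name)
    }
  }
  idx
}

#' @export
print.megakey_matrix <- function(x, ...) {
  cat(sprintf("<coded matrix> %d species x %d characters, %d remark keywords\n",
              length(x$species), length(schema_ids()), length(x$remarks_index)))
  invisible(x)
}

#' Matrix dimensions and accessors
#'
#' @param m A `megakey_matrix`.
#' @return `matrix_species()`: taxon names in row order.
#' @export
matrix_species <- function(m) m$species

#' @rdname matrix_species
#' @param taxon_name Row to extract.
#' @return `matrix_description()`: the stored `megakey_description`.
#' @export
matrix_description <- function(m, taxon_name) {
  d <- m$descriptions[[taxon_name]]
  if (is.null(d)) {
    mk_abort(sprintf("no species '%s' in matrix", taxon_name),
             "megakey_usage_error")
  }
  d
}

#' Keyword search over remarks
#'
#' Returns the species whose combined remark fields (per-character and
#' general) contain every query token. Matching is case-insensitive and
#' token-level (no stemming): searching "wing spot" finds any species whose
#' remarks mention both "wing" and "spot".
#'
#' @param m A `megakey_matrix`.
#' @param query Non-empty query text; tokens are ANDed.
#' @return Character vector of matching taxon names, sorted.
#' @export
keyword_search <- function(m, query) {
  stopifnot(inherits(m, "megakey_matrix"))
  if (!is.character(query) || length(query) != 1 || !nzchar(trimws(query))) {
    mk_abort("query must be non-empty text", "megakey_usage_error")
  }
  toks <- tokenize_remarks(query)
  if (length(toks) == 0) {
    mk_abort("query contains no searchable tokens", "megakey_usage_error")
  }
  hits <- lapply(toks, function(t) m$remarks_index[[t]] %||% character())
  out <- Reduce(intersect, hits)
  sort(out)
}

#' Save / load a coded matrix
#'
#' The persistent form is a versioned JSON container holding each species'
#' JSON-dialect description, so heterogeneous cells (codes, numbers,
#' intervals, setation expressions, unknowns) and all remarks survive a
#' round trip. The remarks index is rebuilt on load.
#'
#' @param m A `megakey_matrix`.
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @return `save_matrix()`: the JSON text, invisibly when `path` is given.
#' @export
save_matrix <- function(m, path = NULL) {
  stopifnot(inherits(m, "megakey_matrix"))
  rows <- lapply(unname(m$descriptions), function(d) {
    jsonlite::parse_json(write_description_json(d))
  })
  txt <- paste0(jsonlite::toJSON(
    list(format = "megakey-matrix", version = 1L, species = rows),
    auto_unbox = TRUE, pretty = TRUE), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @rdname save_matrix
#' @param text Matrix JSON text (alternative to `path`).
#' @return `load_matrix()`: a `megakey_matrix`.
#' @export
load_matrix <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) mk_abort("give text or path", "megakey_usage_error")
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  doc <- tryCatch(jsonlite::parse_json(text),
                  error = function(e) {
                    mk_abort(paste0("corrupt matrix file: ", conditionMessage(e)),
                             "megakey_format_error")
                  })
  if (!is.list(doc) || !identical(doc$format, "megakey-matrix") ||
      !is.list(doc$species)) {
    mk_abort("not a megakey matrix file (missing format marker or species)",
             "megakey_format_error")
  }
  descriptions <- lapply(seq_along(doc$species), function(i) {
    tryCatch(
      parse_description_json(jsonlite::toJSON(doc$species[[i]],
                                              auto_unbox = TRUE),
                             strict = TRUE),
      megakey_error = function(e) {
        mk_abort(sprintf("corrupt matrix record %d: %s", i,
                         conditionMessage(e)),
                 "megakey_format_error")
      })
  })
  build_matrix(descriptions)
}

#' Matrix equality
#' @param a,b `megakey_matrix` objects.
#' @return Logical: same species in the same order with equal descriptions.
#' @export
matrices_equal <- function(a, b) {
  if (!identical(a$species, b$species)) return(FALSE)
  all(vapply(a$species, function(s) {
    descriptions_equal(a$descriptions[[s]], b$descriptions[[s]])
  }, TRUE))
}

#' Flat CSV export of the coded matrix
#'
#' A spreadsheet-friendly view: one row per species, one column per
#' character, cells in their printed form (state labels, rounded numbers,
#' "1-4", "T6~E~H<C", "?"). Lossy: remarks and figure labels are dropped.
#'
#' @param m A `megakey_matrix`.
#' @param path Optional file path.
#' @return The CSV text (invisibly when `path` is given).
#' @export
matrix_csv <- function(m, path = NULL) {
  stopifnot(inherits(m, "megakey_matrix"))
  ids <- schema_ids()
  rows <- lapply(m$species, function(s) {
    d <- m$descriptions[[s]]
    c(taxon_name = s, vapply(ids, function(id) format_value(d$values[[id]]), ""))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  txt <- paste0(paste(csv_out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
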