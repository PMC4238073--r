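# Reading and writing description documents.
#
# Two dialects:
#   tsv  - human-facing, mirroring the printed three-column template
#          (label <TAB> value <TAB> remark) with section headers
#          Head / Thorax / Leg / Wing / Genitalia / General Remarks
#   json - machine-facing, keyed by character id, versioned

DIALECTS <- c("tsv", "json")

tsv_sections <- list(
  head = "Head", thorax = "Thorax", leg = "Leg",
  wing = "Wing", genitalia = "Genitalia"
)

label_lookup <- function() {
  defs <- canonical_schema()
  stats::setNames(names(defs),
                  norm_label(vapply(defs, `[[`, "", "label")))
}

#' Parse a description document
#'
#' Accepts either dialect; by default the dialect is sniffed (a document
#' whose first non-blank character is `{` is JSON, anything else is TSV).
#' Raw cell text is normalized through [encode_value()], so printed aliases
#' ("spinose", "PD", bare "1" for a ratio) are accepted; alias use is
#' recorded as a parse warning. In strict mode (the default) any
#' unparseable cell aborts with an aggregated validation error; in lenient
#' mode such cells become unknown and are recorded as warnings.
#'
#' @param text Document text (single string or character vector of lines).
#' @param dialect `"auto"`, `"tsv"` or `"json"`.
#' @param strict Abort on invalid cells (`TRUE`, default) or downgrade them
#'   to unknowns with warnings (`FALSE`).
#' @return A `megakey_description`; parse warnings, if any, are attached as
#'   a data frame in `attr(, "parse_warnings")`.
#' @export
parse_description <- function(text, dialect = c("auto", "tsv", "json"),
                              strict = TRUE) {
  dialect <- match.arg(dialect)
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("^[[:space:]]*\\{", text)) "json" else "tsv"
  }
  if (dialect == "json") parse_description_json(text, strict)
  else parse_description_tsv(text, strict)
}

#' @rdname parse_description
#' @param path Path to a description file.
#' @export
read_description <- function(path, dialect = c("auto", "tsv", "json"),
                             strict = TRUE) {
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  parse_description(txt, dialect, strict)
}

# shared cell-by-cell assembly with strict/lenient handling
assemble_description <- function(taxon_name, raw_values, character_remarks,
                                 general_remarks, figure_refs, strict,
                                 warnings) {
  ids <- schema_ids()
  missing <- setdiff(ids, names(raw_values))
  if (length(missing)) {
    mk_abort(paste0("document is missing character(s): ",
                    paste(missing, collapse = ", ")),
             "megakey_validation_error")
  }
  vals <- list()
  problems <- list()
  for (id in ids) {
    raw <- raw_values[[id]]
    res <- tryCatch(encode_value(id, raw), megakey_error = function(e) e)
    if (inherits(res, "megakey_value")) {
      vals[[id]] <- res
    } else {
      problems[[length(problems) + 1L]] <- data.frame(
        level = "warning", character_id = id,
        message = sprintf("cannot parse '%s': %s", as.character(raw),
                          conditionMessage(res)),
        stringsAsFactors = FALSE)
      vals[[id]] <- unknown_value(id)
    }
  }
  if (length(problems) && strict) {
    probs <- do.call(rbind, problems)
    msg <- paste0("invalid cell(s):\n",
                  paste(sprintf("  %s: %s", probs$character_id, probs$message),
                        collapse = "\n"))
    mk_abort(msg, "megakey_validation_error")
  }
  d <- description(taxon_name, vals, character_remarks, general_remarks,
                   figure_refs)
  warn <- rbind(warnings, if (length(problems)) do.call(rbind, problems))
  if (!is.null(warn) && nrow(warn)) attr(d, "parse_warnings") <- warn
  d
}

# record printed-alias usage (e.g. Labellum "spinose") as warnings
alias_warnings <- function(raw_values) {
  out <- list()
  for (id in names(raw_values)) {
    def <- character_definition(id)
    raw <- raw_values[[id]]
    if (length(def$aliases) && is.character(raw) && length(raw) == 1) {
      hit <- norm_label(names(def$aliases)) == norm_label(raw)
      if (any(hit)) {
        canon <- state_label(id, def$aliases[[which(hit)[1]]])
        out[[length(out) + 1L]] <- data.frame(
          level = "warning", character_id = id,
          message = sprintf("label '%s' accepted as alias of '%s'", raw, canon),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## ---- TSV dialect --------------------------------------------------------

parse_description_tsv <- function(text, strict) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    mk_abort("document too short to be a description table",
             "megakey_parse_error")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i, j) {
    row <- cells[[i]]
    if (length(row) >= j) row[[j]] else ""
  }
  taxon_name <- trimws(col(1, 1))
  figure_refs <- character()
  if (nzchar(trimws(col(1, 2)))) figure_refs["habitus"] <- trimws(col(1, 2))

  lookup <- label_lookup()
  section_names <- norm_label(unlist(tsv_sections))
  raw_values <- list()
  character_remarks <- character()
  general_lines <- character()
  in_general <- FALSE
  current_section <- NULL
  for (i in 2:length(lines)) {
    first <- trimws(col(i, 1))
    nf <- norm_label(first)
    if (nf == "general remarks") {
      in_general <- TRUE
      next
    }
    if (in_general) {
      general_lines <- c(general_lines, sub("\t.*$", "", lines[[i]]))
      next
    }
    if (nf %in% section_names) {
      current_section <- names(tsv_sections)[match(nf, section_names)]
      fig <- trimws(col(i, 2))
      # col 3 of a section header is the printed "Remarks" column caption
      if (nzchar(fig) && !identical(norm_label(fig), "remarks")) {
        figure_refs[current_section] <- fig
      }
      next
    }
    id <- unname(lookup[norm_label(first)])
    if (length(id) != 1 || is.na(id)) {
      mk_abort(sprintf("line %d: unrecognized character label '%s'", i, first),
               "megakey_parse_error")
    }
    if (!is.null(raw_values[[id]])) {
      mk_abort(sprintf("line %d: character '%s' appears more than once", i, id),
               "megakey_parse_error")
    }
    raw_values[[id]] <- trimws(col(i, 2))
    remark <- col(i, 3)
    if (nzchar(remark)) character_remarks[id] <- remark
  }
  general_remarks <- paste(general_lines, collapse = "\n")
  assemble_description(taxon_name, raw_values, character_remarks,
                       general_remarks, figure_refs, strict,
                       alias_warnings(raw_values))
}

#' Serialize a description
#'
#' Output is deterministic and schema-ordered; `parse_description()` of the
#' output reconstructs an equal description (value-level equality,
#' including remarks and figure labels).
#'
#' @param d A `megakey_description`.
#' @param dialect `"tsv"` or `"json"`.
#' @return Document text (single string).
#' @export
write_description <- function(d, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(d, "megakey_description"))
  if (dialect == "json") return(write_description_json(d))
  write_description_tsv(d)
}

write_description_tsv <- function(d) {
  no_tabs <- c(d$taxon_name, d$general_remarks, d$character_remarks,
               d$figure_refs)
  if (any(grepl("[\t\n]", no_tabs[nzchar(no_tabs)]))) {
    mk_abort("TSV dialect cannot carry tabs or newlines in text fields; use JSON",
             "megakey_validation_error")
  }
  fig <- function(section) {
    f <- d$figure_refs[section]
    if (length(f) == 1 && !is.na(f)) f else ""
  }
  out <- c(sprintf("%s\t%s\t", d$taxon_name, fig("habitus")),
           "Head\t\tRemarks")
  defs <- canonical_schema()
  current_region <- "head"
  for (id in names(defs)) {
    def <- defs[[id]]
    if (def$region != current_region) {
      current_region <- def$region
      header <- tsv_sections[[current_region]]
      out <- c(out, sprintf("%s\t%s\t", header, fig(current_region)))
    }
    remark <- d$character_remarks[id]
    remark <- if (length(remark) == 1 && !is.na(remark)) remark else ""
    out <- c(out, sprintf("%s\t%s\t%s", def$label,
                          format_value(d$values[[id]]), remark))
  }
  out <- c(out, "General Remarks\t\t")
  if (nzchar(d$general_remarks)) out <- c(out, d$general_remarks)
  paste0(paste(out, collapse = "\n"), "\n")
}

## ---- JSON dialect -------------------------------------------------------

write_description_json <- function(d) {
  vals <- lapply(d$values, format_value)
  doc <- list(
    format = "megakey-description",
    version = 1L,
    taxon_name = d$taxon_name,
    values = vals,
    character_remarks = as.list(d$character_remarks),
    general_remarks = d$general_remarks,
    figure_refs = as.list(d$figure_refs)
  )
  paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), "\n")
}

parse_description_json <- function(text, strict) {
  doc <- tryCatch(jsonlite::parse_json(text),
                  error = function(e) {
                    mk_abort(paste0("invalid JSON: ", conditionMessage(e)),
                             "megakey_parse_error")
                  })
  if (!is.list(doc) || is.null(doc$taxon_name) || !is.list(doc$values)) {
    mk_abort("JSON description must carry 'taxon_name' and 'values'",
             "megakey_parse_error")
  }
  raw_values <- doc$values
  extra <- setdiff(names(raw_values), schema_ids())
  if (length(extra)) {
    mk_abort(paste0("unknown character id(s): ", paste(extra, collapse = ", ")),
             "megakey_schema_error")
  }
  character_remarks <- unlist(doc$character_remarks %||% list())
  if (is.null(character_remarks)) character_remarks <- character()
  figure_refs <- unlist(doc$figure_refs %||% list())
  if (is.null(figure_refs)) figure_refs <- character()
  assemble_description(doc$taxon_name, raw_values,
                       character_remarks,
                       doc$general_remarks %||% "",
                       figure_refs, strict,
                       alias_warnings(raw_values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
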