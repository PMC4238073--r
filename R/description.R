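# Description: one taxon's full record — taxon name, all 29 character
# values (possibly unknown), optional per-character and general remarks,
# and opaque figure labels for the habitus, wing and genitalia sections.

#' Construct a description
#'
#' Builds a single-taxon description from raw values. Every schema
#' character must be supplied (use `"?"` for unknowns); raw values are
#' normalized through [encode_value()].
#'
#' @param taxon_name Taxon name text.
#' @param values Named list (or vector) of raw values keyed by character id.
#' @param character_remarks Named character vector of per-character remarks
#'   keyed by character id (omit or empty for none).
#' @param general_remarks Free text, `""` for none.
#' @param figure_refs Named character vector of opaque figure labels keyed
#'   by section (`habitus`, `wing`, `genitalia`).
#' @return A `megakey_description`.
#' @export
description <- function(taxon_name, values, character_remarks = character(),
                        general_remarks = "", figure_refs = character()) {
  if (!is.character(taxon_name) || length(taxon_name) != 1 ||
      !nzchar(trimws(taxon_name))) {
    mk_abort("taxon_name must be a non-empty string", "megakey_validation_error")
  }
  ids <- schema_ids()
  extra <- setdiff(names(values), ids)
  if (length(extra)) {
    mk_abort(paste0("unknown character id(s): ", paste(extra, collapse = ", ")),
             "megakey_schema_error")
  }
  missing <- setdiff(ids, names(values))
  if (length(missing)) {
    mk_abort(paste0("missing character(s): ", paste(missing, collapse = ", ")),
             "megakey_validation_error")
  }
  vals <- lapply(ids, function(id) {
    v <- values[[id]]
    if (inherits(v, "megakey_value")) v else encode_value(id, v)
  })
  names(vals) <- ids
  character_remarks <- character_remarks[nzchar(character_remarks)]
  bad <- setdiff(names(character_remarks), ids)
  if (length(bad)) {
    mk_abort(paste0("remarks for unknown character(s): ",
                    paste(bad, collapse = ", ")), "megakey_schema_error")
  }
  structure(list(taxon_name = taxon_name,
                 values = vals,
                 character_remarks = character_remarks,
                 general_remarks = general_remarks,
                 figure_refs = figure_refs),
            class = "megakey_description")
}

#' @export
print.megakey_description <- function(x, ...) {
  cat(sprintf("<description> %s\n", x$taxon_name))
  known <- sum(!vapply(x$values, is_unknown, TRUE))
  cat(sprintf("  %d/29 characters known", known))
  if (nzchar(x$general_remarks)) cat("; has general remarks")
  cat("\n")
  invisible(x)
}

#' Validate a description against the schema rules
#'
#' Checks structural completeness and every per-character domain rule:
#' coded states must resolve, numeric values must be positive, the midtibial
#' palisade proportion should not exceed 1, the third costal ratio must be
#' exactly 1, the tarsomere palisade interval must sit inside 1..5, and the
#' posterior-setation expression must contain T6, E, C and H exactly once.
#'
#' @param d A `megakey_description`.
#' @return A data frame of findings with columns `level` ("error" or
#'   "warning"), `character_id` and `message`, ordered by schema position.
#'   Zero rows means the description is valid.
#' @export
validate_description <- function(d) {
  stopifnot(inherits(d, "megakey_description"))
  findings <- list()
  add <- function(level, id, msg) {
    findings[[length(findings) + 1L]] <<-
      data.frame(level = level, character_id = id, message = msg,
                 stringsAsFactors = FALSE)
  }
  ids <- schema_ids()
  missing <- setdiff(ids, names(d$values))
  for (id in missing) add("error", id, "character missing from description")
  for (id in intersect(ids, names(d$values))) {
    v <- d$values[[id]]
    if (!inherits(v, "megakey_value") || v$character_id != id) {
      add("error", id, "value is not a typed character value for this character")
      next
    }
    if (is_unknown(v)) next
    def <- character_definition(id)
    switch(
      def$kind,
      coded_categorical = , count = {
        if (!(v$value %in% names(def$states))) {
          add("error", id, sprintf("code '%s' is not a state of this character",
                                   v$value))
        }
      },
      ratio = , proportion = , length_mm = {
        if (id == "costal_ratios") {
          if (length(v$value) != 3 || any(!is.finite(v$value)) ||
              any(v$value <= 0)) {
            add("error", id, "costal ratios must be three positive numbers")
          } else if (v$value[3] != 1) {
            add("error", id, "third costal ratio (C3) must be exactly 1")
          }
        } else if (!is.numeric(v$value) || length(v$value) != 1 ||
                   !is.finite(v$value) || v$value <= 0) {
          add("error", id, "numeric value must be a single positive number")
        } else if (def$kind == "proportion" && v$value > 1) {
          add("warning", id, sprintf("proportion %.2f exceeds 1", v$value))
        }
      },
      segment_range = {
        ok <- is.integer(v$value) && length(v$value) == 2 &&
          v$value[1] <= v$value[2] && v$value[1] >= 1L && v$value[2] <= 5L
        if (!ok) add("error", id, "tarsomere range must be an interval within 1..5")
      },
      order_expression = {
        if (!inherits(v$value, "megakey_setation") ||
            !setequal(v$value$tokens, SETATION_TOKENS)) {
          add("error", id, "setation order must contain T6, E, C and H exactly once")
        }
      }
    )
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(), character_id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  out[order(match(out$character_id, ids)), , drop = FALSE]
}

#' Value-level equality of two descriptions
#'
#' Compares taxon name, every character value (typed, not textual),
#' per-character remarks, general remarks and figure labels.
#'
#' @param a,b `megakey_description` objects.
#' @return Logical.
#' @export
descriptions_equal <- function(a, b) {
  if (!inherits(a, "megakey_description") || !inherits(b, "megakey_description"))
    return(FALSE)
  if (a$taxon_name != b$taxon_name) return(FALSE)
  if (!identical(sort(names(a$values)), sort(names(b$values)))) return(FALSE)
  for (id in names(a$values)) {
    if (!values_equal(a$values[[id]], b$values[[id]])) return(FALSE)
  }
  norm_rem <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0) return(character())
    x[order(names(x))]
  }
  if (!identical(norm_rem(a$character_remarks), norm_rem(b$character_remarks)))
    return(FALSE)
  if (!identical(a$general_remarks, b$general_remarks)) return(FALSE)
  identical(norm_rem(a$figure_refs), norm_rem(b$figure_refs))
}
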