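# CharacterValue: one species' value for one character. The payload depends
# on the character kind:
#   ratio/proportion/length_mm -> double, rounded at the schema precision
#                                 (costal_ratios: length-3 double, third = 1)
#   count                      -> code letter (d = "4+", an open lower bound)
#   coded_categorical          -> code letter
#   segment_range              -> integer c(lo, hi), inclusive, within 1..5
#   order_expression           -> megakey_setation
# The unknown sentinel "?" is permitted for every character.

new_value <- function(character_id, value, unknown = FALSE) {
  structure(list(character_id = character_id,
                 value = value, unknown = unknown),
            class = "megakey_value")
}

#' The unknown ("?") value for a character
#'
#' @param character_id Character id.
#' @return A `megakey_value` flagged unknown.
#' @export
unknown_value <- function(character_id) {
  character_definition(character_id)  # validates the id
  new_value(character_id, NA, unknown = TRUE)
}

#' Is a value unknown?
#' @param v A `megakey_value`.
#' @return Logical.
#' @export
is_unknown <- function(v) isTRUE(v$unknown)

#' Encode a raw observation as a typed character value
#'
#' Dispatches on the character's kind: numeric observations are rounded at
#' the schema precision, categorical labels are resolved case-insensitively
#' (printed aliases such as "spinose" or "PD" are accepted), counts are
#' coded with the "4+" top state, tarsomere ranges accept `"1-4"` / `"3"` /
#' `c(1, 4)`, and setation expressions are parsed. The sentinel `"?"`
#' passes through as an unknown value.
#'
#' @param character_id Character id from [canonical_schema()].
#' @param raw A measurement, count, state label, code letter, serialized
#'   form, or `"?"`.
#' @return A `megakey_value`.
#' @examples
#' encode_value("np_cleft", "present")$value     # "b"
#' encode_value("wing_length_mm", 1.556)$value   # 1.56
#' @export
encode_value <- function(character_id, raw) {
  def <- character_definition(character_id)
  if (is.character(raw) && length(raw) == 1 && trimws(raw) == "?") {
    return(unknown_value(character_id))
  }
  value <- switch(
    def$kind,
    ratio = , proportion = , length_mm = encode_numeric(def, raw),
    count = encode_count(def, raw),
    coded_categorical = encode_coded(def, raw),
    segment_range = encode_range(def, raw),
    order_expression = encode_order(def, raw)
  )
  new_value(character_id, value)
}

encode_numeric <- function(def, raw) {
  if (def$id == "costal_ratios") return(encode_costal_ratios(def, raw))
  if (is.character(raw)) raw <- suppressWarnings(as.numeric(raw))
  if (!is.numeric(raw) || length(raw) != 1 || !is.finite(raw)) {
    mk_abort(sprintf("character '%s' expects a single number", def$id),
             "megakey_invalid_measurement")
  }
  if (raw <= 0) {
    mk_abort(sprintf("character '%s' must be > 0", def$id),
             "megakey_invalid_measurement")
  }
  round_half_up(raw, def$precision)
}

encode_costal_ratios <- function(def, raw) {
  if (is.character(raw) && length(raw) == 1) {
    parts <- strsplit(trimws(raw), ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      mk_abort("costal ratios must have three sections 'C1:C2:C3'",
               "megakey_invalid_measurement")
    }
    raw <- suppressWarnings(as.numeric(parts))
  }
  if (!is.numeric(raw) || length(raw) != 3 || any(!is.finite(raw)) ||
      any(raw <= 0)) {
    mk_abort("costal ratios must be three positive numbers",
             "megakey_invalid_measurement")
  }
  # third section is the unit of measure; re-normalize if not already 1
  c(round_half_up(raw[1] / raw[3], 2L), round_half_up(raw[2] / raw[3], 2L), 1)
}

encode_count <- function(def, raw) {
  if (is.character(raw)) {
    r <- trimws(raw)
    if (r %in% names(def$states)) return(r)
    lab_hit <- which(vapply(def$states, identity, "") == r)
    if (length(lab_hit) == 1) return(names(def$states)[lab_hit])
    raw <- suppressWarnings(as.numeric(r))
  }
  if (!is.numeric(raw) || length(raw) != 1 || !is.finite(raw)) {
    mk_abort(sprintf("character '%s' expects an integer count", def$id),
             "megakey_invalid_measurement")
  }
  classify_alular_count(raw)$code
}

encode_coded <- function(def, raw) {
  if (is.numeric(raw) && length(raw) == 1) raw <- format(raw)
  if (!is.character(raw) || length(raw) != 1) {
    mk_abort(sprintf("character '%s' expects a state label", def$id),
             "megakey_unknown_state_error")
  }
  r <- trimws(raw)
  # a bare code letter is accepted as-is
  if (nchar(r) == 1 && r %in% names(def$states)) return(r)
  state_code(def$id, r)
}

encode_range <- function(def, raw) {
  if (is.character(raw) && length(raw) == 1) {
    r <- gsub("[[:space:]]", "", raw)
    m <- regexec("^([0-9]+)(?:[-–]([0-9]+))?$", r)
    g <- regmatches(r, m)[[1]]
    if (length(g) == 0) {
      mk_abort(sprintf("cannot parse tarsomere range '%s'", raw),
               "megakey_invalid_measurement")
    }
    lo <- as.integer(g[2])
    hi <- if (nzchar(g[3])) as.integer(g[3]) else lo
    raw <- c(lo, hi)
  }
  if (!is.numeric(raw) || length(raw) > 2 || any(raw != trunc(raw))) {
    mk_abort("tarsomere range must be one or two integers",
             "megakey_invalid_measurement")
  }
  if (length(raw) == 1) raw <- c(raw, raw)
  raw <- as.integer(raw)
  if (raw[1] > raw[2] || raw[1] < 1 || raw[2] > 5) {
    mk_abort("tarsomere range must be an ordered interval within 1..5",
             "megakey_invalid_measurement")
  }
  raw
}

encode_order <- function(def, raw) {
  if (inherits(raw, "megakey_setation")) return(raw)
  parse_setation_order(raw)
}

#' Serialize a character value as its printed table form
#'
#' Numeric values are printed at the schema precision, coded values as
#' their canonical state label, costal ratios as `"C1:C2:1"`, tarsomere
#' ranges as `"1-4"` (a single segment as `"3"`), setation orders as their
#' expression, and unknowns as `"?"`.
#'
#' @param v A `megakey_value`.
#' @return A single string.
#' @export
format_value <- function(v) {
  stopifnot(inherits(v, "megakey_value"))
  if (is_unknown(v)) return("?")
  def <- character_definition(v$character_id)
  switch(
    def$kind,
    ratio = , proportion = , length_mm = {
      if (def$id == "costal_ratios") {
        sprintf("%.2f:%.2f:1", v$value[1], v$value[2])
      } else {
        sprintf(paste0("%.", def$precision, "f"), v$value)
      }
    },
    count = ,
    coded_categorical = state_label(def$id, v$value),
    segment_range = if (v$value[1] == v$value[2]) {
      as.character(v$value[1])
    } else {
      sprintf("%d-%d", v$value[1], v$value[2])
    },
    order_expression = render_setation_order(v$value)
  )
}

#' @export
print.megakey_value <- function(x, ...) {
  cat(sprintf("<value> %s = %s\n", x$character_id, format_value(x)))
  invisible(x)
}

#' @export
format.megakey_value <- function(x, ...) format_value(x)

# value-level equality (used by round-trip checks and matrix equality)
values_equal <- function(a, b) {
  if (a$character_id != b$character_id) return(FALSE)
  if (is_unknown(a) || is_unknown(b)) return(is_unknown(a) && is_unknown(b))
  def <- character_definition(a$character_id)
  switch(
    def$kind,
    ratio = , proportion = , length_mm =
      length(a$value) == length(b$value) && all(a$value == b$value),
    count = ,
    coded_categorical = identical(a$value, b$value),
    segment_range = identical(a$value, b$value),
    order_expression = identical(a$value$tokens, b$value$tokens) &&
      identical(a$value$ops, b$value$ops)
  )
}
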