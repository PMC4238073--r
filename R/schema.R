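# Canonical 29-character Megaselia description schema.
#
# Character kinds:
#   ratio / proportion / length_mm  - numeric, recorded to 2 decimals
#   count                           - integer count stored as a coded letter,
#                                     with an open-ended top state ("4+")
#   coded_categorical               - single-letter coded states a, b, c, ...
#   segment_range                   - inclusive tarsomere interval, e.g. "1-4"
#   order_expression                - relative-setation expression over
#                                     T6, E, C, H, e.g. "T6~E~H<C"

mk_def <- function(id, label, region, kind, states = list(), units = "",
                   precision = if (kind %in% c("ratio", "proportion", "length_mm")) 2L else NA_integer_,
                   aliases = character()) {
  structure(
    list(id = id, label = label, region = region, kind = kind,
         states = states, units = units, precision = precision,
         aliases = aliases),
    class = "megakey_definition"
  )
}

st <- function(...) {
  labs <- c(...)
  codes <- letters[seq_along(labs)]
  stats::setNames(as.list(labs), codes)
}

.schema_build <- function() {
  defs <- list(
    ## Head ----------------------------------------------------------------
    mk_def("sa_ratio", "SA ratio", "head", "ratio"),
    mk_def("vif_position", "VIF position", "head", "coded_categorical",
           states = st("normal", "VFO adjacent")),
    mk_def("sps_vesicles", "SPS vesicles", "head", "coded_categorical",
           states = st("absent", "present")),
    mk_def("palpal_setae", "Palpal setae length", "head", "coded_categorical",
           states = st("long", "short")),
    mk_def("labellum", "Labellum spinosity", "head", "coded_categorical",
           states = st("not spinose", "sparse", "dense"),
           aliases = c("spinose" = "c", "not" = "a")),
    ## Thorax --------------------------------------------------------------
    mk_def("anepisternum", "Anepisternum", "thorax", "coded_categorical",
           states = st("bare", "hairs only", "hairs + bristles"),
           aliases = c("hairs + bristle(s)" = "c")),
    # the printed template letters "lighter" (a) and "darker" (c); "same"
    # carries no letter in print and is assigned "b" to keep codes contiguous
    mk_def("halter_color", "Relative halter color", "thorax", "coded_categorical",
           states = st("lighter", "same", "darker")),
    mk_def("np_setae_count", "# NP setae", "thorax", "coded_categorical",
           states = st("2", "3")),
    mk_def("np_cleft", "NP cleft", "thorax", "coded_categorical",
           states = st("absent", "present")),
    mk_def("scutellar_setae", "Scutellar setae", "thorax", "coded_categorical",
           states = st("4 =", "4 /=", "2+2")),
    ## Leg -----------------------------------------------------------------
    mk_def("ts1_palisade", "ts1 palisade", "leg", "segment_range"),
    mk_def("t2_palisade", "t2 palisade", "leg", "proportion"),
    mk_def("t3_comb_bifurcate", "t3 comb bifurcate", "leg", "coded_categorical",
           states = st("absent", "present")),
    mk_def("t3_setulae", "t3 setulae", "leg", "coded_categorical",
           states = st("PD only", "PD + AD"),
           aliases = c("PD" = "a", "PD+AD" = "b")),
    mk_def("f3_basal_setae", "f3 basal setae", "leg", "coded_categorical",
           states = st("B<AV", "B=AV", "B>AV")),
    mk_def("f3_basal_differentiation", "f3 basal setae differentiation", "leg",
           "coded_categorical", states = st("absent", "present")),
    ## Wing ----------------------------------------------------------------
    mk_def("wing_length_mm", "Wing Length (mm)", "wing", "length_mm", units = "mm"),
    mk_def("subcosta", "Subcosta", "wing", "coded_categorical",
           states = st("complete", "incomplete")),
    mk_def("hair_at_base_r", "Hair at base of R", "wing", "coded_categorical",
           states = st("absent", "minute", "short", "long")),
    mk_def("r2_3", "R_2+3", "wing", "coded_categorical",
           states = st("present", "absent")),
    mk_def("costal_index", "Costal index", "wing", "ratio"),
    mk_def("costal_ratios", "Costal ratios", "wing", "ratio"),
    mk_def("costal_setae_mm", "Costal setae length (mm)", "wing", "length_mm",
           units = "mm"),
    mk_def("alular_setae_count", "Number alular setae", "wing", "count",
           states = st("1", "2", "3", "4+")),
    mk_def("alular_setae_mm", "Alular setae length (mm)", "wing", "length_mm",
           units = "mm"),
    mk_def("wing_color", "Wing color", "wing", "coded_categorical",
           states = st("lightly infuscated/clear", "strongly infuscated"),
           aliases = c("lightly infuscated" = "a", "clear" = "a")),
    ## Genitalia -----------------------------------------------------------
    mk_def("at_length", "AT length", "genitalia", "coded_categorical",
           states = st("AT<E", "AT=E", "AT>E")),
    mk_def("e_setation", "E setation", "genitalia", "coded_categorical",
           states = st("hairs only", "hairs + bristles"),
           aliases = c("hairs + bristle(s)" = "b")),
    mk_def("posterior_setation", "Relative posterior setation", "genitalia",
           "order_expression")
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  defs
}

.schema <- .schema_build()

#' The canonical Megaselia description schema
#'
#' Returns the 29 character definitions of the table-based description
#' system, in template order (Head, Thorax, Leg, Wing, Genitalia). Each
#' definition records the character's stable id, display label, body region,
#' value kind, coded states (for categorical and count kinds), units and
#' recording precision.
#'
#' @return A named list of 29 `megakey_definition` objects, named by
#'   character id, in schema order.
#' @examples
#' length(canonical_schema())
#' canonical_schema()[["labellum"]]$states
#' @export
canonical_schema <- function() .schema

#' @rdname canonical_schema
#' @return `schema_ids()`: character vector of the 29 ids in schema order.
#' @export
schema_ids <- function() names(.schema)

#' Look up one character definition
#'
#' @param character_id Stable character id, e.g. `"sa_ratio"`.
#' @return A `megakey_definition`.
#' @export
character_definition <- function(character_id) {
  def <- .schema[[character_id]]
  if (is.null(def)) {
    mk_abort(sprintf("unknown character id '%s'", character_id),
             "megakey_schema_error")
  }
  def
}

#' Resolve coded states
#'
#' `state_label()` maps a code letter to its state label; `state_code()`
#' maps a state label (case-insensitively, aliases accepted) to its code.
#'
#' @param character_id Character id with coded states.
#' @param code Single code letter.
#' @param label State label text.
#' @return A single string (label or code letter).
#' @export
state_label <- function(character_id, code) {
  def <- character_definition(character_id)
  lab <- def$states[[code]]
  if (is.null(lab)) {
    mk_abort(sprintf("character '%s' has no state coded '%s'", character_id, code),
             "megakey_schema_error")
  }
  lab
}

#' @rdname state_label
#' @export
state_code <- function(character_id, label) {
  def <- character_definition(character_id)
  if (length(def$states) == 0) {
    mk_abort(sprintf("character '%s' has no coded states", character_id),
             "megakey_schema_error")
  }
  norm <- norm_label(label)
  labs <- vapply(def$states, identity, "")
  hit <- which(norm_label(labs) == norm)
  if (length(hit) == 1) return(names(def$states)[hit])
  ali <- def$aliases[norm_label(names(def$aliases)) == norm]
  if (length(ali) == 1) return(unname(ali))
  mk_abort(sprintf("'%s' is not a state of character '%s' (valid: %s)",
                   label, character_id, paste(labs, collapse = ", ")),
           "megakey_unknown_state_error")
}

# collapse case and runs of whitespace so printed labels match template labels
norm_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' @export
print.megakey_definition <- function(x, ...) {
  cat(sprintf("<character '%s'> %s [%s, %s]\n", x$id, x$label, x$region, x$kind))
  if (length(x$states)) {
    for (code in names(x$states)) {
      cat(sprintf("  %s: %s\n", code, x$states[[code]]))
    }
  }
  if (!is.na(x$precision)) {
    cat(sprintf("  recorded to %d decimals%s\n", x$precision,
                if (nzchar(x$units)) paste0(" (", x$units, ")") else ""))
  }
  invisible(x)
}

#' Export the schema as a versioned JSON document
#'
#' Serializes the canonical schema (ids, labels, regions, kinds, coded
#' states, units, precisions) so other tools can consume the format
#' definition.
#'
#' @return A JSON string.
#' @export
schema_json <- function() {
  defs <- lapply(unname(.schema), function(d) {
    list(id = d$id, label = d$label, region = d$region, kind = d$kind,
         states = if (length(d$states)) {
           lapply(names(d$states), function(code) {
             list(code = code, label = d$states[[code]])
           })
         } else list(),
         units = d$units,
         precision = if (is.na(d$precision)) NULL else d$precision)
  })
  jsonlite::toJSON(list(format = "megakey-schema", version = 1L,
                        characters = defs),
                   auto_unbox = TRUE, pretty = TRUE, null = "null")
}

## ---- measurement / classification rules --------------------------------

check_positive <- function(..., .what = "measurement") {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    mk_abort(sprintf("%s must be finite and > 0", .what),
             "megakey_invalid_measurement")
  }
  invisible(TRUE)
}

# round half away from zero at the recording precision; all schema
# quantities are positive so this is round-half-up
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Supra-antennal seta ratio
#'
#' The length of the ventral supra-antennal (SA) seta as a fraction of the
#' dorsal SA, recorded to two decimals. Equal setae give 1.00; a ventral SA
#' half the dorsal length gives 0.50.
#'
#' @param ventral_length,dorsal_length Seta lengths in any one consistent
#'   unit; both must be positive.
#' @return The ratio ventral/dorsal, rounded to 2 decimals.
#' @examples
#' compute_sa_ratio(0.05, 0.10)
#' @export
compute_sa_ratio <- function(ventral_length, dorsal_length) {
  check_positive(ventral_length, dorsal_length, .what = "SA seta length")
  round_half_up(ventral_length / dorsal_length, 2L)
}

#' Classify labellum spinosity
#'
#' A labellum without spinose setulae is "not spinose" (a); with scattered
#' setulae numbering fewer than 30 per labellum it is "sparse" (b); with 30
#' or more it is "dense" (c).
#'
#' @param setulae_per_labellum Non-negative integer count of spinose
#'   setulae on one labellum. Ignored (treated as 0) when `spinose = FALSE`.
#' @param spinose Are spinose setulae present at all?
#' @return A `megakey_state` (code + label) for character `labellum`.
#' @examples
#' classify_labellum(12, TRUE)$code   # "b"
#' @export
classify_labellum <- function(setulae_per_labellum, spinose) {
  if (!isTRUE(spinose) && !isFALSE(spinose)) {
    mk_abort("'spinose' must be TRUE or FALSE", "megakey_invalid_measurement")
  }
  n <- if (spinose) setulae_per_labellum else 0
  if (!is.finite(n) || n < 0) {
    mk_abort("setulae count must be a non-negative number",
             "megakey_invalid_measurement")
  }
  code <- if (!spinose) "a" else if (n < 30) "b" else "c"
  mk_state("labellum", code)
}

#' Classify palpal seta length
#'
#' "long" (a) if the longest palpal seta is strictly longer than the width
#' of the palpus, "short" (b) otherwise (a seta exactly as long as the palp
#' is wide is "short").
#'
#' @param seta_length,palp_width Positive lengths in one consistent unit.
#' @return A `megakey_state` for character `palpal_setae`.
#' @export
classify_palpal_setae <- function(seta_length, palp_width) {
  check_positive(seta_length, palp_width, .what = "palpal measurement")
  mk_state("palpal_setae", if (seta_length > palp_width) "a" else "b")
}

#' Classify the hair at the base of vein R
#'
#' "absent" (a) when no hair is present; otherwise "minute" (b) up to the
#' width of the vein, "short" (c) above one and up to two vein widths, and
#' "long" (d) strictly beyond twice the vein width.
#'
#' @param hair_length,vein_width Positive lengths in one consistent unit
#'   (ignored when `present = FALSE`).
#' @param present Is the hair present?
#' @return A `megakey_state` for character `hair_at_base_r`.
#' @export
classify_hair_at_base_r <- function(hair_length, vein_width, present) {
  if (!isTRUE(present) && !isFALSE(present)) {
    mk_abort("'present' must be TRUE or FALSE", "megakey_invalid_measurement")
  }
  if (!present) return(mk_state("hair_at_base_r", "a"))
  check_positive(hair_length, vein_width, .what = "hair/vein measurement")
  code <- if (hair_length <= vein_width) "b"
          else if (hair_length <= 2 * vein_width) "c"
          else "d"
  mk_state("hair_at_base_r", code)
}

#' Costal index
#'
#' The length of the costal vein relative to the wing length, recorded to
#' two decimals. Note the classical verbal definition is sometimes quoted
#' the other way around; the convention used throughout this system is
#' costa/wing, which keeps the index below 1 (e.g. 0.65).
#'
#' @param costa_length,wing_length Positive lengths in one consistent unit;
#'   the costa cannot exceed the wing.
#' @return costa/wing rounded to 2 decimals.
#' @examples
#' compute_costal_index(1.014, 1.56)
#' @export
compute_costal_index <- function(costa_length, wing_length) {
  check_positive(costa_length, wing_length, .what = "wing measurement")
  if (costa_length > wing_length) {
    mk_abort("costa length cannot exceed wing length",
             "megakey_invalid_measurement")
  }
  round_half_up(costa_length / wing_length, 2L)
}

#' Costal section ratios
#'
#' The three successive costal sections are reported as "C1:C2:C3" with C3
#' fixed at 1 and the first two given to two decimals.
#'
#' @param c1,c2,c3 Positive section lengths in one consistent unit.
#' @return Numeric vector `c(C1/C3, C2/C3, 1)` with the first two rounded
#'   to 2 decimals and the third identically 1.
#' @examples
#' compute_costal_ratios(2.5, 2.0, 2.0)
#' @export
compute_costal_ratios <- function(c1, c2, c3) {
  check_positive(c1, c2, c3, .what = "costal section length")
  c(round_half_up(c1 / c3, 2L), round_half_up(c2 / c3, 2L), 1)
}

#' Code the alular seta count
#'
#' Alular setae are counted and coded "1" (a), "2" (b), "3" (c) or "4+" (d);
#' counts of four or more collapse into the open-ended top state because of
#' observed variation at high counts. A count of zero has no defined code
#' and raises an error.
#'
#' @param n Integer count of alular setae, at least 1.
#' @return A `megakey_state` for character `alular_setae_count`.
#' @export
classify_alular_count <- function(n) {
  if (!is.finite(n) || n != trunc(n) || n < 0) {
    mk_abort("alular seta count must be a non-negative integer",
             "megakey_invalid_measurement")
  }
  if (n == 0) {
    cond <- structure(
      class = c("megakey_unsupported_state", "megakey_error", "error", "condition"),
      list(message = "no code is defined for 0 alular setae", call = NULL,
           raw_count = 0L))
    stop(cond)
  }
  code <- if (n >= 4) "d" else c("a", "b", "c")[n]
  mk_state("alular_setae_count", code)
}

## ---- small shared infrastructure ---------------------------------------

mk_state <- function(character_id, code) {
  structure(list(character_id = character_id, code = code,
                 label = state_label(character_id, code)),
            class = "megakey_state")
}

#' @export
print.megakey_state <- function(x, ...) {
  cat(sprintf("<state> %s = %s ('%s')\n", x$character_id, x$code, x$label))
  invisible(x)
}

mk_abort <- function(message, class) {
  stop(structure(class = c(class, "megakey_error", "error", "condition"),
                 list(message = message, call = NULL)))
}
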