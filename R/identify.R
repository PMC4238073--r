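# Tolerance-aware matching of a (possibly partial) query description
# against a coded matrix, plus the entropy-based best-next-character
# suggester of a multi-access key.

#' Tolerance configuration for identification
#'
#' Numeric characters (ratios, proportions, lengths) tolerate a relative
#' deviation from the recorded matrix value; counts tolerate an absolute
#' slack; coded characters must match exactly but a small number of
#' categorical disagreements can be budgeted before a species stops being a
#' candidate. Per-character overrides replace the kind-level tolerance for
#' that character (relative for numeric kinds, absolute for counts).
#'
#' @param relative_tolerance Fraction applied to numeric characters,
#'   measured relative to the matrix (reference) value. Default 0.10.
#' @param absolute_count_tolerance Integer slack on counts. Default 0.
#' @param categorical_mismatch_budget Maximum categorical disagreements a
#'   species may show and still be reported as a candidate. Default 0.
#' @param overrides Named numeric vector/list, character id -> tolerance.
#' @return A `megakey_tolerance`.
#' @export
tolerance_config <- function(relative_tolerance = 0.10,
                             absolute_count_tolerance = 0L,
                             categorical_mismatch_budget = 0L,
                             overrides = list()) {
  if (relative_tolerance < 0 || absolute_count_tolerance < 0 ||
      categorical_mismatch_budget < 0) {
    mk_abort("tolerances must be >= 0", "megakey_usage_error")
  }
  overrides <- as.list(overrides)
  bad <- setdiff(names(overrides), schema_ids())
  if (length(bad)) {
    mk_abort(paste0("tolerance overrides for unknown character(s): ",
                    paste(bad, collapse = ", ")), "megakey_usage_error")
  }
  if (length(overrides) && any(unlist(overrides) < 0)) {
    mk_abort("tolerances must be >= 0", "megakey_usage_error")
  }
  structure(list(relative_tolerance = relative_tolerance,
                 absolute_count_tolerance = absolute_count_tolerance,
                 categorical_mismatch_budget = categorical_mismatch_budget,
                 overrides = overrides),
            class = "megakey_tolerance")
}

tol_for <- function(tol, character_id, default) {
  ov <- tol$overrides[[character_id]]
  if (is.null(ov)) default else ov
}

# code letter -> count for the "4+"-style coding; "d" is an open bound
count_from_code <- function(code) match(code, c("a", "b", "c", "d"))

#' Per-character compatibility verdict
#'
#' Decides whether a query value is compatible with a reference (matrix)
#' value under the tolerance configuration:
#' * unknown on either side: `"unknown"` (skipped);
#' * coded states: compatible iff the codes are equal;
#' * numeric: compatible iff `|q - r| <= tol * r` (tolerance relative to
#'   the reference; costal ratios are compared section-wise);
#' * counts: compatible iff the counts differ by at most the absolute
#'   slack, with "4+" standing for any count of four or more;
#' * tarsomere ranges: compatible iff the intervals are identical;
#' * setation orders: compatible iff no token pair is strictly ordered in
#'   opposite directions (equal and subequal rank never contradict).
#'
#' @param query_value,reference_value `megakey_value` objects for the same
#'   character.
#' @param tol A `megakey_tolerance`.
#' @return `"compatible"`, `"incompatible"` or `"unknown"`.
#' @export
character_compatibility <- function(query_value, reference_value,
                                    tol = tolerance_config()) {
  stopifnot(inherits(query_value, "megakey_value"),
            inherits(reference_value, "megakey_value"))
  if (query_value$character_id != reference_value$character_id) {
    mk_abort("query and reference values belong to different characters",
             "megakey_usage_error")
  }
  if (is_unknown(query_value) || is_unknown(reference_value)) {
    return("unknown")
  }
  def <- character_definition(query_value$character_id)
  ok <- switch(
    def$kind,
    coded_categorical = identical(query_value$value, reference_value$value),
    ratio = , proportion = , length_mm = {
      rel <- tol_for(tol, def$id, tol$relative_tolerance)
      q <- query_value$value
      r <- reference_value$value
      all(abs(q - r) <= rel * r + 1e-12)
    },
    count = {
      slack <- tol_for(tol, def$id, tol$absolute_count_tolerance)
      qc <- count_from_code(query_value$value)
      rc <- count_from_code(reference_value$value)
      if (qc == 4L && rc == 4L) TRUE                 # both "4+"
      else if (qc == 4L) rc + slack >= 4             # some count >= 4 is reachable
      else if (rc == 4L) qc + slack >= 4
      else abs(qc - rc) <= slack
    },
    segment_range = identical(query_value$value, reference_value$value),
    order_expression = setation_compatible(query_value$value,
                                           reference_value$value)
  )
  if (ok) "compatible" else "incompatible"
}

# numeric kinds disqualify outright when out of tolerance; coded, range and
# order mismatches count against the categorical budget; count mismatches
# beyond the absolute slack disqualify like numerics
kind_class <- function(kind) {
  switch(kind,
         ratio = , proportion = , length_mm = , count = "measured",
         "categorical")
}

#' Build a query from raw values
#'
#' Convenience constructor for a partial query: characters not mentioned
#' are unknown.
#'
#' @param ... Raw values named by character id (or a single named list).
#' @return A named list of `megakey_value` objects covering all 29
#'   characters.
#' @export
query_values <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.list(args[[1]])) {
    args <- args[[1]]
  }
  bad <- setdiff(names(args), schema_ids())
  if (length(bad)) {
    mk_abort(paste0("unknown character id(s): ", paste(bad, collapse = ", ")),
             "megakey_schema_error")
  }
  vals <- lapply(schema_ids(), function(id) {
    if (id %in% names(args)) {
      v <- args[[id]]
      if (inherits(v, "megakey_value")) v else encode_value(id, v)
    } else unknown_value(id)
  })
  stats::setNames(vals, schema_ids())
}

as_query <- function(query) {
  if (inherits(query, "megakey_description")) return(query$values)
  if (is.list(query) && length(query) &&
      all(vapply(query, inherits, TRUE, "megakey_value"))) {
    vals <- lapply(schema_ids(), function(id) query[[id]] %||% unknown_value(id))
    return(stats::setNames(vals, schema_ids()))
  }
  query_values(query)
}

#' Match a query against a coded matrix
#'
#' Every species receives a verdict per query character and a result row.
#' Candidates are species whose categorical disagreements stay within the
#' budget and whose measured characters (numerics and counts) are all
#' within tolerance; non-candidates are kept but ranked after every
#' candidate, supporting a narrow-down-then-confirm workflow. Ordering is
#' deterministic: candidates first, then by mismatch count, unknown count
#' and taxon name, with ranks 1..n.
#'
#' @param query A `megakey_description`, a list from [query_values()], or a
#'   named list of raw values. At least one character must be known.
#' @param m A `megakey_matrix`.
#' @param tol A `megakey_tolerance`.
#' @return A data frame of class `megakey_match` with columns `rank`,
#'   `taxon_name`, `candidate`, `mismatch_count`, `unknown_count`;
#'   per-character verdicts are in `attr(, "verdicts")` (a named list of
#'   named character vectors).
#' @export
match_descriptions <- function(query, m, tol = tolerance_config()) {
  stopifnot(inherits(m, "megakey_matrix"))
  qvals <- as_query(query)
  known <- names(qvals)[!vapply(qvals, is_unknown, TRUE)]
  if (length(known) == 0) {
    mk_abort("query has no known characters", "megakey_usage_error")
  }
  ids <- schema_ids()
  rows <- lapply(m$species, function(s) {
    d <- m$descriptions[[s]]
    verdicts <- vapply(ids, function(id) {
      character_compatibility(qvals[[id]], d$values[[id]], tol)
    }, "")
    inc <- names(verdicts)[verdicts == "incompatible"]
    classes <- vapply(inc, function(id) kind_class(character_definition(id)$kind), "")
    cat_mis <- sum(classes == "categorical")
    meas_mis <- sum(classes == "measured")
    list(taxon_name = s,
         verdicts = verdicts,
         mismatch_count = length(inc),
         unknown_count = sum(verdicts == "unknown"),
         candidate = cat_mis <= tol$categorical_mismatch_budget && meas_mis == 0)
  })
  mis <- vapply(rows, `[[`, 0L, "mismatch_count")
  unk <- vapply(rows, `[[`, 0L, "unknown_count")
  cand <- vapply(rows, `[[`, TRUE, "candidate")
  nm <- vapply(rows, `[[`, "", "taxon_name")
  ord <- order(!cand, mis, unk, nm)
  out <- data.frame(rank = seq_along(ord),
                    taxon_name = nm[ord],
                    candidate = cand[ord],
                    mismatch_count = mis[ord],
                    unknown_count = unk[ord],
                    stringsAsFactors = FALSE)
  attr(out, "verdicts") <- stats::setNames(lapply(rows[ord], `[[`, "verdicts"),
                                           nm[ord])
  class(out) <- c("megakey_match", class(out))
  out
}

#' @export
print.megakey_match <- function(x, ...) {
  cat(sprintf("<match> %d species, %d candidate(s)\n",
              nrow(x), sum(x$candidate)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

## ---- best next character ------------------------------------------------

shannon_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# bin signature of a value for entropy purposes; numeric characters are
# binned in tolerance-width windows so values the matcher would not
# distinguish fall in one bin
value_signature <- function(v, def, tol, scale) {
  if (is_unknown(v)) return(NA_character_)
  switch(
    def$kind,
    coded_categorical = , count = v$value,
    ratio = , proportion = , length_mm = {
      rel <- tol_for(tol, def$id, tol$relative_tolerance)
      w <- rel * scale
      if (!is.finite(w) || w <= 0) {
        paste(format(v$value), collapse = ":")
      } else {
        paste(floor(v$value / w), collapse = ":")
      }
    },
    segment_range = sprintf("%d-%d", v$value[1], v$value[2]),
    order_expression = paste(v$value$ranks[SETATION_TOKENS], collapse = ",")
  )
}

#' Suggest the most discriminating next character
#'
#' Among the unanswered characters, returns the one whose state
#' distribution over the surviving species has maximal Shannon entropy
#' (numeric characters are binned in tolerance-width windows anchored at
#' the survivors' median value; unknown cells are left out of the
#' distribution). Ties break by schema order. When no unanswered character
#' separates any survivors (or none is left), an exhausted-key condition
#' of class `megakey_exhausted_key` is signalled.
#'
#' @param m A `megakey_matrix`.
#' @param surviving Character vector of surviving taxon names (>= 2).
#' @param answered Character ids already answered.
#' @param tol A `megakey_tolerance` (controls numeric binning).
#' @return A character id.
#' @export
next_best_character <- function(m, surviving, answered = character(),
                                tol = tolerance_config()) {
  stopifnot(inherits(m, "megakey_matrix"))
  surviving <- intersect(m$species, surviving)
  if (length(surviving) < 2) {
    mk_abort("need at least two surviving species", "megakey_usage_error")
  }
  open <- setdiff(schema_ids(), answered)
  if (length(open) == 0) {
    mk_abort("all characters answered", "megakey_exhausted_key")
  }
  ent <- vapply(open, function(id) {
    def <- character_definition(id)
    vals <- lapply(surviving, function(s) m$descriptions[[s]]$values[[id]])
    scale <- if (def$kind %in% c("ratio", "proportion", "length_mm")) {
      known <- unlist(lapply(vals, function(v) if (is_unknown(v)) NULL else v$value[1]))
      if (length(known)) stats::median(known) else 1
    } else 1
    sig <- vapply(vals, value_signature, "", def = def, tol = tol, scale = scale)
    shannon_entropy(table(sig[!is.na(sig)]))
  }, 0)
  if (max(ent) <= 0) {
    mk_abort("no unanswered character separates the surviving species",
             "megakey_exhausted_key")
  }
  open[which.max(ent)]
}
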