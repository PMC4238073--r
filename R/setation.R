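# Relative posterior setation expressions.
#
# The relative lengths of setae on tergite 6 (T6), epandrium (E), cerci (C)
# and hypoproct (H) are written as an ascending chain joined by the
# operators "<" (less than), "=" (equal) and "~" (subequal), e.g.
# "T6~E~H<C". "=" and "~" both place their operands at the same rank; the
# distinction is kept only for rendering.

SETATION_TOKENS <- c("T6", "E", "C", "H")

#' Parse a relative-setation expression
#'
#' @param expression Expression text such as `"T6<C=H<E"`.
#' @param partial Allow a subset of the four tokens (used when comparing a
#'   query constraint against a full record). By default all of T6, E, C
#'   and H must appear exactly once.
#' @return A `megakey_setation` with fields `tokens` (as written), `ops`
#'   (operators between adjacent tokens), `groups` (list of equal-rank
#'   token sets, ascending) and `ranks` (named integer rank per token).
#' @examples
#' parse_setation_order("T6~E~H<C")$groups
#' @export
parse_setation_order <- function(expression, partial = FALSE) {
  if (!is.character(expression) || length(expression) != 1 ||
      is.na(expression) || !nzchar(trimws(expression))) {
    mk_abort("empty setation expression", "megakey_parse_error")
  }
  txt <- gsub("[[:space:]]+", "", expression)
  pieces <- regmatches(txt, gregexpr("T6|E|C|H|[<=~]", txt))[[1]]
  if (sum(nchar(pieces)) != nchar(txt)) {
    bad <- regexpr("[^T6ECH<=~]", txt)
    mk_abort(sprintf("unexpected character at position %d in '%s'", bad, txt),
             "megakey_parse_error")
  }
  is_op <- pieces %in% c("<", "=", "~")
  # must alternate token, op, token, op, ...
  if (length(pieces) %% 2 == 0 ||
      any(is_op != (seq_along(pieces) %% 2 == 0))) {
    mk_abort(sprintf("malformed setation expression '%s'", expression),
             "megakey_parse_error")
  }
  tokens <- pieces[!is_op]
  ops <- pieces[is_op]
  if (anyDuplicated(tokens)) {
    dup <- tokens[duplicated(tokens)][1]
    mk_abort(sprintf("duplicated token '%s' in '%s'", dup, expression),
             "megakey_parse_error")
  }
  if (!partial && !setequal(tokens, SETATION_TOKENS)) {
    missing <- setdiff(SETATION_TOKENS, tokens)
    mk_abort(sprintf("missing token(s) %s in '%s'",
                     paste(missing, collapse = ", "), expression),
             "megakey_parse_error")
  }
  ranks <- integer(length(tokens))
  r <- 1L
  for (i in seq_along(ops)) {
    ranks[i] <- r
    if (ops[i] == "<") r <- r + 1L
  }
  ranks[length(tokens)] <- r
  names(ranks) <- tokens
  groups <- lapply(split(tokens, ranks), identity)
  names(groups) <- NULL
  structure(list(tokens = tokens, ops = ops, groups = groups, ranks = ranks),
            class = "megakey_setation")
}

#' Render a setation expression
#'
#' The canonical rendering reproduces the parsed input exactly, including
#' the choice between "=" and "~".
#'
#' @param x A `megakey_setation`.
#' @return The expression string.
#' @export
render_setation_order <- function(x) {
  stopifnot(inherits(x, "megakey_setation"))
  n <- length(x$tokens)
  out <- character(2L * n - 1L)
  out[seq(1, 2 * n - 1, by = 2)] <- x$tokens
  if (n > 1) out[seq(2, 2 * n - 2, by = 2)] <- x$ops
  paste(out, collapse = "")
}

#' @export
print.megakey_setation <- function(x, ...) {
  cat("<setation order>", render_setation_order(x), "\n")
  invisible(x)
}

#' @export
format.megakey_setation <- function(x, ...) render_setation_order(x)

# Strict-order sign for a token pair under an expression: -1 if a is ranked
# below b, +1 if above, 0 if equal rank or either token absent.
setation_pair_sign <- function(ord, a, b) {
  ra <- ord$ranks[a]; rb <- ord$ranks[b]
  if (is.na(ra) || is.na(rb)) return(0L)
  sign(as.integer(ra) - as.integer(rb))
}

# Two expressions are compatible unless some token pair is strictly ordered
# in opposite directions ("~"/"=" are both equal rank and never contradict
# a strict order).
setation_compatible <- function(a, b) {
  toks <- intersect(names(a$ranks), names(b$ranks))
  if (length(toks) < 2) return(TRUE)
  prs <- utils::combn(toks, 2, simplify = FALSE)
  for (p in prs) {
    sa <- setation_pair_sign(a, p[1], p[2])
    sb <- setation_pair_sign(b, p[1], p[2])
    if (sa != 0L && sb != 0L && sa != sb) return(FALSE)
  }
  TRUE
}
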