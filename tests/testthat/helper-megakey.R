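# Shared fixtures and independent oracles for the test suite.

shadeae_path <- function() {
  p <- system.file("extdata", "megaselia_shadeae.tsv", package = "megakey")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata",
                                 "megaselia_shadeae.tsv")
  p
}

read_shadeae <- function() read_description(shadeae_path())

# a complete, valid set of raw values (the worked example's states) that
# individual tests override field by field
base_raw_values <- function() {
  list(
    sa_ratio = 1.00, vif_position = "VFO adjacent", sps_vesicles = "absent",
    palpal_setae = "long", labellum = "dense",
    anepisternum = "bare", halter_color = "same", np_setae_count = "2",
    np_cleft = "absent", scutellar_setae = "2+2",
    ts1_palisade = "1-4", t2_palisade = 0.67, t3_comb_bifurcate = "absent",
    t3_setulae = "PD only", f3_basal_setae = "B<AV",
    f3_basal_differentiation = "absent",
    wing_length_mm = 1.56, subcosta = "incomplete", hair_at_base_r = "long",
    r2_3 = "present", costal_index = 0.65, costal_ratios = c(1.25, 1.00, 1),
    costal_setae_mm = 0.09, alular_setae_count = 3, alular_setae_mm = 0.15,
    wing_color = "strongly infuscated",
    at_length = "AT>E", e_setation = "hairs only",
    posterior_setation = "T6~E~H<C"
  )
}

make_description <- function(taxon_name = "Megaselia testis", ...) {
  raw <- utils::modifyList(base_raw_values(), list(...))
  description(taxon_name, raw)
}

# all permutations of a small vector (for the exhaustive setation suite)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
  }))
}

# ---- independent zero-tolerance matching oracle -------------------------
# Equality-based brute force, written without the package's compatibility
# engine: cells are compared through their printed forms, except setation
# orders, whose rank structure is recomputed here from the raw expression
# ("=" and "~" both keep the rank level; "<" raises it).

oracle_ranks <- function(expression) {
  toks <- strsplit(expression, "[<=~]")[[1]]
  ops <- strsplit(gsub("T6|E|C|H", "", expression), "")[[1]]
  lvl <- cumsum(c(0, ops == "<"))
  stats::setNames(lvl, toks)
}

oracle_cell_equal <- function(id, qv, rv) {
  kind <- canonical_schema()[[id]]$kind
  if (kind == "order_expression") {
    # strict-order consistency: enumerate every token pair and fail only on
    # opposing strict orders (equal/subequal rank never contradicts)
    rq <- oracle_ranks(render_setation_order(qv$value))
    rr <- oracle_ranks(render_setation_order(rv$value))
    toks <- c("T6", "E", "C", "H")
    for (i in 1:3) for (j in (i + 1):4) {
      sq <- sign(rq[[toks[i]]] - rq[[toks[j]]])
      sr <- sign(rr[[toks[i]]] - rr[[toks[j]]])
      if (sq != 0 && sr != 0 && sq != sr) return(FALSE)
    }
    return(TRUE)
  }
  identical(format_value(qv), format_value(rv))
}

oracle_match <- function(query_description, m) {
  qvals <- query_description$values
  rows <- lapply(m$species, function(s) {
    d <- m$descriptions[[s]]
    mis <- 0L; unk <- 0L
    for (id in schema_ids()) {
      qv <- qvals[[id]]; rv <- d$values[[id]]
      if (is_unknown(qv) || is_unknown(rv)) {
        unk <- unk + 1L
      } else if (!oracle_cell_equal(id, qv, rv)) {
        mis <- mis + 1L
      }
    }
    data.frame(taxon_name = s, mismatch_count = mis, unknown_count = unk,
               candidate = mis == 0L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(!df$candidate, df$mismatch_count, df$unknown_count,
                 df$taxon_name), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
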