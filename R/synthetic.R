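# Synthetic species descriptions with controlled statistical structure,
# for exercising the matrix and identification engine without collection
# data. Taxon names are explicitly labelled synthetic.

# coded columns used for pairwise separation / Hamming distance: every
# character stored as a single code letter
coded_ids <- function() {
  defs <- canonical_schema()
  names(defs)[vapply(defs, function(d)
    d$kind %in% c("coded_categorical", "count"), TRUE)]
}

default_numeric_ranges <- function() {
  # intervals bracket the worked-example measurements rather than claiming
  # genus-wide realism
  list(
    sa_ratio = c(0.30, 1.20),
    t2_palisade = c(0.40, 0.95),
    wing_length_mm = c(0.80, 3.00),
    costal_index = c(0.45, 0.85),
    costal_ratios = c(0.60, 2.50),   # sampled independently for C1 and C2
    costal_setae_mm = c(0.03, 0.20),
    alular_setae_mm = c(0.05, 0.30)
  )
}

# remark vocabulary for synthetic species; deliberately avoids the tokens
# "wing" and "spot" so keyword retrieval of the real worked example stays
# unambiguous in mixed matrices
synthetic_remark_pool <- c(
  "legs darkened", "halter knob pale", "frons shining",
  "costa thickened", "scutellum with long setulae", "palpi enlarged"
)

#' Generator configuration
#'
#' @param n_species Number of species to generate.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param numeric_ranges Named list of `c(low, high)` sampling intervals
#'   per numeric character; defaults bracket the worked example (e.g. wing
#'   length 0.8--3.0 mm).
#' @param categorical_weights Named list, character id -> non-negative
#'   weight per coded state (default uniform).
#' @param min_pairwise_separation Minimum number of coded characters in
#'   which any two generated species differ. Default 3.
#' @param unknown_rate Probability that a cell is recorded unknown ("?").
#'   Default 0.
#' @param remark_rate Probability that a species carries a general remark
#'   drawn from a small synthetic vocabulary. Default 0.3.
#' @return A `megakey_generator_config`.
#' @export
generator_config <- function(n_species, seed,
                             numeric_ranges = list(),
                             categorical_weights = list(),
                             min_pairwise_separation = 3L,
                             unknown_rate = 0,
                             remark_rate = 0.3) {
  if (n_species < 1) mk_abort("n_species must be >= 1", "megakey_usage_error")
  ranges <- utils::modifyList(default_numeric_ranges(), numeric_ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      mk_abort(sprintf("numeric range for '%s' must be positive and ordered", nm),
               "megakey_usage_error")
    }
  }
  bad <- setdiff(names(categorical_weights), coded_ids())
  if (length(bad)) {
    mk_abort(paste0("weights for non-coded character(s): ",
                    paste(bad, collapse = ", ")), "megakey_usage_error")
  }
  for (nm in names(categorical_weights)) {
    w <- categorical_weights[[nm]]
    nstates <- length(character_definition(nm)$states)
    if (length(w) != nstates || any(w < 0) || sum(w) <= 0) {
      mk_abort(sprintf("weights for '%s' must be %d non-negative values with a positive sum",
                       nm, nstates), "megakey_usage_error")
    }
  }
  if (unknown_rate < 0 || unknown_rate >= 1) {
    mk_abort("unknown_rate must be in [0, 1)", "megakey_usage_error")
  }
  if (min_pairwise_separation < 0 ||
      min_pairwise_separation > length(coded_ids())) {
    mk_abort("min_pairwise_separation out of range", "megakey_usage_error")
  }
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 numeric_ranges = ranges,
                 categorical_weights = categorical_weights,
                 min_pairwise_separation = as.integer(min_pairwise_separation),
                 unknown_rate = unknown_rate,
                 remark_rate = remark_rate),
            class = "megakey_generator_config")
}

sample_one_description <- function(cfg, taxon_name) {
  defs <- canonical_schema()
  ranges <- cfg$numeric_ranges
  raw <- list()
  for (id in names(defs)) {
    def <- defs[[id]]
    raw[[id]] <- switch(
      def$kind,
      coded_categorical = , count = {
        w <- cfg$categorical_weights[[id]]
        if (is.null(w)) w <- rep(1, length(def$states))
        code <- sample(names(def$states), 1, prob = w)
        if (def$kind == "count") state_label(id, code) else
          new_value(id, code)
      },
      ratio = , proportion = , length_mm = {
        if (id == "costal_ratios") {
          r <- ranges$costal_ratios
          c(stats::runif(1, r[1], r[2]), stats::runif(1, r[1], r[2]), 1)
        } else {
          r <- ranges[[id]]
          stats::runif(1, r[1], r[2])
        }
      },
      # palisades run from the tarsomere base; vary the distal extent
      segment_range = c(1L, sample.int(5L, 1)),
      order_expression = {
        toks <- sample(SETATION_TOKENS)
        ops <- sample(c("<", "=", "~"), 3, replace = TRUE)
        paste0(toks[1], ops[1], toks[2], ops[2], toks[3], ops[3], toks[4])
      }
    )
  }
  if (cfg$unknown_rate > 0) {
    drop <- stats::runif(length(raw)) < cfg$unknown_rate
    for (i in which(drop)) raw[[i]] <- "?"
  }
  general <- ""
  if (cfg$remark_rate > 0 && stats::runif(1) < cfg$remark_rate) {
    general <- sample(synthetic_remark_pool, 1)
  }
  description(taxon_name, raw, general_remarks = general)
}

#' Coded Hamming distance between two descriptions
#'
#' Number of coded characters (single-letter states, including the alular
#' count code) in which two descriptions carry different known states;
#' cells unknown on either side do not count.
#'
#' @param a,b `megakey_description` objects.
#' @return Integer distance.
#' @export
coded_distance <- function(a, b) {
  sum(vapply(coded_ids(), function(id) {
    va <- a$values[[id]]; vb <- b$values[[id]]
    !is_unknown(va) && !is_unknown(vb) && !identical(va$value, vb$value)
  }, TRUE))
}

#' Generate synthetic species descriptions
#'
#' Draws `n_species` valid descriptions with every two species differing in
#' at least `min_pairwise_separation` coded characters (rejection
#' sampling). Output is fully reproducible from the configured seed.
#'
#' @param cfg A `megakey_generator_config`.
#' @return List of `megakey_description` objects named
#'   `Megaselia sp-synth-001`, `...-002`, etc.
#' @export
generate_species <- function(cfg) {
  stopifnot(inherits(cfg, "megakey_generator_config"))
  withr::with_seed(cfg$seed, {
    out <- list()
    attempts <- 0L
    while (length(out) < cfg$n_species) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        mk_abort(paste0("could not reach the pairwise separation floor within ",
                        "10000 attempts; lower min_pairwise_separation or n_species"),
                 "megakey_generation_error")
      }
      nm <- sprintf("Megaselia sp-synth-%03d", length(out) + 1L)
      cand <- sample_one_description(cfg, nm)
      far_enough <- all(vapply(out, function(d)
        coded_distance(cand, d) >= cfg$min_pairwise_separation, TRUE))
      if (far_enough) out[[length(out) + 1L]] <- cand
    }
    names(out) <- vapply(out, `[[`, "", "taxon_name")
    out
  })
}

#' Perturb a description
#'
#' Simulates observing another specimen of the same species: every numeric
#' value is multiplied by an independent factor drawn uniformly from
#' `[1 - numeric_noise, 1 + numeric_noise]` and re-rounded at the schema
#' precision, and exactly `flip_count` coded characters (chosen uniformly
#' among the known ones) are switched to a different valid state chosen
#' uniformly. Ranges and setation orders are untouched. The result still
#' validates.
#'
#' @param d A `megakey_description`.
#' @param numeric_noise Non-negative noise fraction.
#' @param flip_count Number of coded characters to flip.
#' @param seed Integer seed.
#' @return A perturbed `megakey_description` (same taxon name and remarks).
#' @export
perturb_description <- function(d, numeric_noise, flip_count, seed) {
  stopifnot(inherits(d, "megakey_description"))
  if (numeric_noise < 0) {
    mk_abort("numeric_noise must be >= 0", "megakey_usage_error")
  }
  flippable <- Filter(function(id) !is_unknown(d$values[[id]]), coded_ids())
  if (flip_count < 0 || flip_count > length(flippable)) {
    mk_abort("flip_count out of range for this description",
             "megakey_usage_error")
  }
  withr::with_seed(seed, {
    vals <- d$values
    for (id in names(vals)) {
      v <- vals[[id]]
      if (is_unknown(v)) next
      def <- character_definition(id)
      if (def$kind %in% c("ratio", "proportion", "length_mm") &&
          numeric_noise > 0) {
        if (id == "costal_ratios") {
          f <- stats::runif(2, 1 - numeric_noise, 1 + numeric_noise)
          vals[[id]] <- new_value(id, c(round_half_up(v$value[1] * f[1], 2L),
                                        round_half_up(v$value[2] * f[2], 2L), 1))
        } else {
          f <- stats::runif(1, 1 - numeric_noise, 1 + numeric_noise)
          vals[[id]] <- new_value(id, round_half_up(v$value * f, def$precision))
        }
      }
    }
    if (flip_count > 0) {
      flip <- sample(flippable, flip_count)
      for (id in flip) {
        def <- character_definition(id)
        others <- setdiff(names(def$states), vals[[id]]$value)
        vals[[id]] <- new_value(id, sample(others, 1))
      }
    }
    description(d$taxon_name, vals, d$character_remarks, d$general_remarks,
                d$figure_refs)
  })
}
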