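test_that("numeric compatibility is relative to the reference value", {
  tol <- tolerance_config(relative_tolerance = 0.10)
  q <- encode_value("wing_length_mm", 1.60)
  r <- encode_value("wing_length_mm", 1.56)
  expect_identical(character_compatibility(q, r, tol), "compatible")
  q2 <- encode_value("wing_length_mm", 1.72)   # |1.72-1.56| = 0.16 > 0.156
  expect_identical(character_compatibility(q2, r, tol), "incompatible")
  # window anchored at the reference, not the query
  expect_identical(
    character_compatibility(encode_value("wing_length_mm", 1.10),
                            encode_value("wing_length_mm", 1.00),
                            tol),
    "compatible")
  expect_identical(
    character_compatibility(encode_value("wing_length_mm", 1.115),
                            encode_value("wing_length_mm", 1.00), tol),
    "incompatible")
  expect_error(character_compatibility(q, encode_value("sa_ratio", 1)),
               class = "megakey_usage_error")
})

test_that("unknowns are skipped, counts honor '4+', ranges and orders compare structurally", {
  tol <- tolerance_config()
  expect_identical(
    character_compatibility(unknown_value("subcosta"),
                            encode_value("subcosta", "complete"), tol),
    "unknown")
  expect_identical(
    character_compatibility(encode_value("subcosta", "complete"),
                            unknown_value("subcosta"), tol),
    "unknown")
  cc <- function(a, b, t = tol) character_compatibility(
    encode_value("alular_setae_count", a), encode_value("alular_setae_count", b), t)
  expect_identical(cc(7, 4), "compatible")      # both "4+"
  expect_identical(cc(3, 3), "compatible")
  expect_identical(cc(3, 4), "incompatible")
  expect_identical(cc(3, 4, tolerance_config(absolute_count_tolerance = 1)),
                   "compatible")
  expect_identical(cc(2, 4, tolerance_config(absolute_count_tolerance = 1)),
                   "incompatible")
  expect_identical(
    character_compatibility(encode_value("ts1_palisade", "1-4"),
                            encode_value("ts1_palisade", "1-3"), tol),
    "incompatible")
  so <- function(a, b) character_compatibility(
    encode_value("posterior_setation", a),
    megakey:::new_value("posterior_setation",
                        parse_setation_order(b, partial = TRUE)), tol)
  expect_identical(so("T6~E~H<C", "C<T6"), "incompatible")
  expect_identical(so("T6~E~H<C", "T6=E=H<C"), "compatible")
  expect_identical(so("T6<E<C<H", "T6~E<C<H"), "compatible")
})

test_that("an identity query ranks its own species first with zero mismatches", {
  d <- read_shadeae()
  cfg <- generator_config(n_species = 10, seed = 9)
  m <- build_matrix(c(list(d), generate_species(cfg)))
  res <- match_descriptions(d, m)
  expect_identical(res$taxon_name[1], "Megaselia shadeae")
  expect_identical(res$mismatch_count[1], 0L)
  expect_identical(res$unknown_count[1], 0L)
  expect_identical(res$rank, seq_len(nrow(res)))
})

test_that("a single contradicted character gives one mismatch and demotes the species", {
  m <- build_matrix(list(read_shadeae()))
  res <- match_descriptions(query_values(r2_3 = "absent"), m)
  expect_identical(res$mismatch_count[1], 1L)
  expect_false(res$candidate[1])
  v <- attr(res, "verdicts")[["Megaselia shadeae"]]
  expect_identical(unname(v["r2_3"]), "incompatible")
  expect_identical(sum(v == "unknown"), 28L)
  expect_error(match_descriptions(query_values(), m),
               class = "megakey_usage_error")
})

test_that("a +5% perturbed query recovers its species at rank 1 in a 50-species matrix", {
  cfg <- generator_config(n_species = 50, seed = 7)
  sp <- generate_species(cfg)
  m <- build_matrix(sp)
  q <- perturb_description(sp[[17]], 0.05, 0, seed = 7)
  res <- match_descriptions(q, m, tolerance_config(relative_tolerance = 0.10))
  expect_identical(res$taxon_name[1], sp[[17]]$taxon_name)
  expect_identical(res$mismatch_count[1], 0L)
  # brute-force check: no other species is fully compatible
  expect_identical(sum(res$candidate), 1L)
})

test_that("with zero tolerances matching equals the exact-equality oracle", {
  tol0 <- tolerance_config(0, 0L, 0L)
  cfg <- generator_config(n_species = 6, seed = 21,
                          min_pairwise_separation = 1, unknown_rate = 0.05)
  m <- build_matrix(generate_species(cfg))
  qcfg <- generator_config(n_species = 5, seed = 22,
                           min_pairwise_separation = 0, unknown_rate = 0.3)
  for (q in generate_species(qcfg)) {
    got <- match_descriptions(q, m, tol0)
    want <- oracle_match(q, m)
    expect_identical(got$taxon_name, want$taxon_name)
    expect_identical(got$mismatch_count, want$mismatch_count)
    expect_identical(got$unknown_count, want$unknown_count)
    expect_identical(got$candidate, want$candidate)
  }
})

test_that("enlarging tolerances never increases any mismatch count", {
  cfg <- generator_config(n_species = 12, seed = 31,
                          min_pairwise_separation = 1)
  sp <- generate_species(cfg)
  m <- build_matrix(sp)
  q <- perturb_description(sp[[4]], 0.15, 2, seed = 99)
  tols <- list(tolerance_config(0, 0L), tolerance_config(0.05, 0L),
               tolerance_config(0.10, 1L), tolerance_config(0.30, 2L))
  prev <- NULL
  for (tol in tols) {
    res <- match_descriptions(q, m, tol)
    cur <- stats::setNames(res$mismatch_count, res$taxon_name)[m$species]
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("unknown query characters never change verdicts on known ones", {
  cfg <- generator_config(n_species = 8, seed = 41, min_pairwise_separation = 1)
  sp <- generate_species(cfg)
  m <- build_matrix(sp)
  q_small <- query_values(subcosta = "incomplete", wing_length_mm = 1.2)
  q_big <- query_values(subcosta = "incomplete", wing_length_mm = 1.2,
                        sps_vesicles = "?", labellum = "?", costal_index = "?")
  r1 <- match_descriptions(q_small, m)
  r2 <- match_descriptions(q_big, m)
  v1 <- attr(r1, "verdicts")
  v2 <- attr(r2, "verdicts")
  for (s in m$species) {
    expect_identical(v1[[s]][c("subcosta", "wing_length_mm")],
                     v2[[s]][c("subcosta", "wing_length_mm")])
  }
})

test_that("next_best_character maximizes entropy and signals exhaustion", {
  base <- base_raw_values()
  mk <- function(name, ...) {
    description(name, utils::modifyList(base, list(...)))
  }
  # only np_setae_count separates the survivors
  m1 <- build_matrix(list(mk("sp A", np_setae_count = "2"),
                          mk("sp B", np_setae_count = "3"),
                          mk("sp C", np_setae_count = "3")))
  expect_identical(next_best_character(m1, matrix_species(m1)),
                   "np_setae_count")
  # identical on all unanswered characters -> exhausted key
  m2 <- build_matrix(list(mk("sp A"), mk("sp B")))
  expect_error(next_best_character(m2, matrix_species(m2)),
               class = "megakey_exhausted_key")
  expect_error(next_best_character(m1, matrix_species(m1),
                                   answered = schema_ids()),
               class = "megakey_exhausted_key")
  # hand-computed entropies over a 3-species toy table:
  #   np_setae_count states (2,3,3):      H = -(1/3)ln(1/3) - (2/3)ln(2/3) = 0.6365
  #   scutellar_setae states (4=,4/=,2+2): H = ln 3              = 1.0986
  m3 <- build_matrix(list(
    mk("sp A", np_setae_count = "2", scutellar_setae = "4 ="),
    mk("sp B", np_setae_count = "3", scutellar_setae = "4 /="),
    mk("sp C", np_setae_count = "3", scutellar_setae = "2+2")))
  expect_identical(next_best_character(m3, matrix_species(m3)),
                   "scutellar_setae")
})

test_that("tolerance configuration rejects bad input and honors overrides", {
  expect_error(tolerance_config(-0.1), class = "megakey_usage_error")
  expect_error(tolerance_config(overrides = list(nope = 0.1)),
               class = "megakey_usage_error")
  tol <- tolerance_config(relative_tolerance = 0,
                          overrides = list(wing_length_mm = 0.2))
  expect_identical(
    character_compatibility(encode_value("wing_length_mm", 1.7),
                            encode_value("wing_length_mm", 1.56), tol),
    "compatible")
  expect_identical(
    character_compatibility(encode_value("costal_index", 0.66),
                            encode_value("costal_index", 0.65), tol),
    "incompatible")
})
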