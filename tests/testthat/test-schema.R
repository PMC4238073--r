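test_that("canonical schema has 29 characters in template order with sound codings", {
  defs <- canonical_schema()
  expect_length(defs, 29)
  expect_identical(names(defs)[1], "sa_ratio")
  expect_identical(names(defs)[29], "posterior_setation")
  regions <- vapply(defs, `[[`, "", "region")
  expect_identical(
    as.vector(table(factor(regions, levels = c(
      "head", "thorax", "leg", "wing", "genitalia")))),
    c(5L, 5L, 6L, 10L, 3L))
  # regions appear as contiguous blocks in template order
  expect_identical(unique(regions),
                   c("head", "thorax", "leg", "wing", "genitalia"))
  for (def in defs) {
    if (length(def$states)) {
      codes <- names(def$states)
      expect_identical(codes, letters[seq_along(codes)], info = def$id)
      expect_gte(length(codes), 2)
    }
    if (def$kind %in% c("ratio", "proportion", "length_mm")) {
      expect_length(def$states, 0)
      expect_identical(def$precision, 2L)
    }
    if (def$kind == "coded_categorical") {
      expect_gte(length(def$states), 2)
    }
  }
  expect_identical(defs$np_setae_count$states, list(a = "2", b = "3"))
  expect_identical(defs$alular_setae_count$states,
                   list(a = "1", b = "2", c = "3", d = "4+"))
})

test_that("state code/label resolution is a bijection over all coded states", {
  for (def in canonical_schema()) {
    for (code in names(def$states)) {
      lab <- state_label(def$id, code)
      expect_identical(state_code(def$id, lab), code)
      expect_identical(state_code(def$id, toupper(lab)), code)
      # encode(label) then decode(code) is the identity
      v <- encode_value(def$id, lab)
      expect_identical(state_label(def$id, v$value), lab)
    }
  }
  expect_error(state_label("labellum", "z"), class = "megakey_schema_error")
  expect_error(state_code("labellum", "fuzzy"),
               class = "megakey_unknown_state_error")
  expect_error(character_definition("nope"), class = "megakey_schema_error")
})

test_that("SA ratio is ventral/dorsal to two decimals", {
  expect_identical(compute_sa_ratio(0.10, 0.10), 1.00)
  expect_identical(compute_sa_ratio(0.05, 0.10), 0.50)
  expect_identical(compute_sa_ratio(0.033, 0.10), 0.33)
  expect_error(compute_sa_ratio(0, 0.1), class = "megakey_invalid_measurement")
  expect_error(compute_sa_ratio(0.1, -1), class = "megakey_invalid_measurement")
})

test_that("labellum classifier uses the sparse/dense threshold at 30 setulae", {
  expect_identical(classify_labellum(0, FALSE)$code, "a")
  expect_identical(classify_labellum(120, FALSE)$code, "a")
  expect_identical(classify_labellum(29, TRUE)$code, "b")
  expect_identical(classify_labellum(30, TRUE)$code, "c")
  # boundary scan: strictly fewer than 30 is sparse, everything above dense
  codes <- vapply(0:100, function(n) classify_labellum(n, TRUE)$code, "")
  expect_identical(codes, ifelse(0:100 < 30, "b", "c"))
  expect_error(classify_labellum(-1, TRUE), class = "megakey_invalid_measurement")
})

test_that("palpal setae are long only when strictly longer than the palp width", {
  expect_identical(classify_palpal_setae(0.12, 0.10)$code, "a")
  expect_identical(classify_palpal_setae(0.10, 0.10)$code, "b")
  expect_identical(classify_palpal_setae(0.05, 0.10)$code, "b")
  expect_error(classify_palpal_setae(0, 1), class = "megakey_invalid_measurement")
})

test_that("hair at base of R classifies by vein-width multiples with closed upper bounds", {
  expect_identical(classify_hair_at_base_r(NA, NA, FALSE)$code, "a")
  expect_identical(classify_hair_at_base_r(0.015, 0.010, TRUE)$code, "c")
  expect_identical(classify_hair_at_base_r(0.021, 0.010, TRUE)$code, "d")
  # boundary scan over hair/width multiples
  mult <- c(0.5, 1.0, 1.5, 2.0, 2.1)
  codes <- vapply(mult, function(k)
    classify_hair_at_base_r(k * 0.01, 0.01, TRUE)$code, "")
  expect_identical(codes, c("b", "b", "c", "c", "d"))
  expect_error(classify_hair_at_base_r(0, 0.01, TRUE),
               class = "megakey_invalid_measurement")
})

test_that("costal index is costa/wing and rejects a costa longer than the wing", {
  expect_identical(compute_costal_index(1.014, 1.56), 0.65)
  expect_identical(compute_costal_index(1.0, 1.0), 1.00)
  expect_identical(compute_costal_index(0.5, 2.0), 0.25)
  expect_error(compute_costal_index(2.0, 1.5),
               class = "megakey_invalid_measurement")
})

test_that("costal ratios normalize on C3 and are scale invariant", {
  expect_identical(compute_costal_ratios(2.5, 2.0, 2.0), c(1.25, 1.00, 1))
  expect_identical(compute_costal_ratios(1, 1, 1), c(1.00, 1.00, 1))
  expect_identical(compute_costal_ratios(0.333, 0.667, 1.0), c(0.33, 0.67, 1))
  set.seed(11)
  for (i in 1:25) {
    cs <- stats::runif(3, 0.2, 3)
    k <- stats::runif(1, 0.1, 50)
    base <- compute_costal_ratios(cs[1], cs[2], cs[3])
    expect_identical(base[3], 1)
    expect_identical(compute_costal_ratios(k * cs[1], k * cs[2], k * cs[3]),
                     base)
  }
  expect_error(compute_costal_ratios(1, 0, 1),
               class = "megakey_invalid_measurement")
})

test_that("alular counts code 1/2/3 and collapse >=4 into the open state", {
  expect_identical(classify_alular_count(3)$code, "c")
  expect_identical(classify_alular_count(1)$code, "a")
  expect_identical(classify_alular_count(7)$code, "d")
  expect_identical(classify_alular_count(4)$code, "d")
  expect_error(classify_alular_count(0), class = "megakey_unsupported_state")
  err <- tryCatch(classify_alular_count(0), condition = identity)
  expect_identical(err$raw_count, 0L)
  expect_error(classify_alular_count(2.5), class = "megakey_invalid_measurement")
})

test_that("classifiers are total over numeric grids away from documented error cases", {
  for (n in 0:60) expect_no_error(classify_labellum(n, TRUE))
  grid <- seq(0.01, 0.5, by = 0.01)
  for (x in grid) {
    expect_no_error(classify_palpal_setae(x, 0.1))
    expect_no_error(classify_hair_at_base_r(x, 0.1, TRUE))
    expect_no_error(compute_sa_ratio(x, 0.25))
  }
})

test_that("encode_value dispatches per kind and applies precision once", {
  expect_identical(encode_value("np_cleft", "present")$value, "b")
  expect_identical(encode_value("scutellar_setae", "2+2")$value, "c")
  expect_identical(encode_value("wing_length_mm", 1.556)$value, 1.56)
  expect_identical(encode_value("np_setae_count", 2)$value, "a")
  expect_identical(encode_value("alular_setae_count", "4+")$value, "d")
  expect_identical(encode_value("alular_setae_count", 9)$value, "d")
  expect_identical(encode_value("ts1_palisade", "1-4")$value, c(1L, 4L))
  expect_identical(encode_value("ts1_palisade", "3")$value, c(3L, 3L))
  expect_identical(encode_value("costal_ratios", "1.25:1.00:1")$value,
                   c(1.25, 1.00, 1))
  expect_true(is_unknown(encode_value("sps_vesicles", "?")))
  expect_error(encode_value("not_a_character", 1), class = "megakey_schema_error")
  err <- tryCatch(encode_value("labellum", "bushy"), condition = identity)
  expect_s3_class(err, "megakey_unknown_state_error")
  expect_match(conditionMessage(err), "not spinose")
})

test_that("printed aliases resolve to canonical states", {
  expect_identical(encode_value("labellum", "spinose")$value, "c")
  expect_identical(encode_value("t3_setulae", "PD")$value, "a")
  expect_identical(encode_value("t3_setulae", "PD+AD")$value, "b")
  expect_identical(encode_value("wing_color", "clear")$value, "a")
})

test_that("schema JSON export is versioned and complete", {
  doc <- jsonlite::parse_json(schema_json())
  expect_identical(doc$format, "megakey-schema")
  expect_length(doc$characters, 29)
  ids <- vapply(doc$characters, `[[`, "", "id")
  expect_identical(ids, schema_ids())
  lab <- doc$characters[[which(ids == "labellum")]]
  expect_identical(vapply(lab$states, `[[`, "", "label"),
                   c("not spinose", "sparse", "dense"))
})
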