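# megakey

Table-based species descriptions and multi-access identification for
*Megaselia* (Diptera: Phoridae).

*Megaselia* is one of the largest genera in the animal kingdom — roughly
half of all scuttle-fly species — and the great majority of its species are
undescribed. Classical verbose descriptions ("light brown" vs "brown",
"medium long" vs "medium short") make both describing new species and
scanning the existing literature painfully slow. `megakey` implements a
streamlined alternative aimed at taxonomists processing large samples: each
species is a single table of 29 well-defined, objectively coded characters,
supplemented by remarks for rare features, and the resulting coded matrix
doubles as a searchable, tolerance-aware multi-access identification key.

## The character system

The 29 characters span five body regions (5 head, 5 thorax, 6 leg, 10 wing,
3 male genitalia) and seven value kinds:

* **ratios / proportions / lengths** recorded to two decimals — e.g. the
  supra-antennal (SA) seta ratio (ventral/dorsal length), the costal index
  CI = costa length / wing length, the midtibial palisade extent, wing
  length in mm;
* **coded categorical states** — single letters `a`, `b`, `c`, … with fixed
  meanings, e.g. labellum spinosity: *not spinose* (a), *sparse* (b, spinose
  setulae numbering fewer than 30 per labellum), *dense* (c, 30 or more);
* **counts** with an open-ended top state — alular setae `1` (a), `2` (b),
  `3` (c), `4+` (d);
* **costal section ratios** `C1:C2:C3` normalized so that C3 = 1;
* **tarsomere intervals** for the foretarsal palisade, e.g. `1-4`;
* **setation order expressions** over tergite 6 (T6), epandrium (E), cerci
  (C) and hypoproct (H), e.g. `T6~E~H<C`, with operators `<` (less than),
  `=` (equal) and `~` (subequal).

Every character may carry a free-text remark; rare but unambiguous features
("wing spot", "large fork") live in remarks and are retrieved by keyword
search rather than occupying a coded column. The identification engine
matches a partial query against the matrix with built-in tolerance —
relative windows on numeric characters (default ±10% of the recorded
value), absolute slack on counts, and a mismatch budget for coded states —
and ranks every species so that near-misses are narrowed down rather than
discarded, to be confirmed against visual aids. Setation expressions are
compared by strict-order consistency, so `T6~E~H<C` and `E~T6~H<C` agree
while `C<T6` contradicts both.

## Worked example

The package ships a transcription of a published one-species table (the
spotted-wing *M. shadeae*) at `inst/extdata/megaselia_shadeae.tsv`:

```r
library(megakey)

d <- read_description(system.file("extdata", "megaselia_shadeae.tsv",
                                  package = "megakey"))
d
#> <description> Megaselia shadeae
#>   29/29 characters known; has general remarks
format_value(d$values$costal_index)        # "0.65"
format_value(d$values$costal_ratios)       # "1.25:1.00:1"
format_value(d$values$posterior_setation)  # "T6~E~H<C"

# mix it into a synthetic fauna and search / identify
fauna <- generate_species(generator_config(n_species = 12, seed = 101))
m <- build_matrix(c(fauna, list(d)))
m
#> <coded matrix> 13 species x 29 characters, 13 remark keywords

keyword_search(m, "wing spot")
#> [1] "Megaselia shadeae"

res <- match_descriptions(
  query_values(r2_3 = "present", wing_length_mm = 1.6, labellum = "dense"),
  m)
head(res, 3)
#>  rank             taxon_name candidate mismatch_count unknown_count
#>     1      Megaselia shadeae      TRUE              0            26
#>     2 Megaselia sp-synth-008      TRUE              0            26
#>     3 Megaselia sp-synth-005     FALSE              1            26

next_best_character(m, res$taxon_name[res$candidate])
#> [1] "sa_ratio"
```

Three answered characters leave two candidates (the query's wing length
1.60 mm sits inside the ±10% window around the recorded 1.56 mm); the
engine then suggests the SA ratio as the most discriminating character to
examine next. A command-line front end with the same operations is
installed as `exec/megakey` (`megakey validate`, `megakey search`,
`megakey identify`, …).

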