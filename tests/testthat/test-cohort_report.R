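# Per-diagnosis fixtures (yield_fixture, origin_fixture in the helper) are
# built from the published per-stratum counts; total rows must then be
# reproduced by the table builders.

test_that("demographics table summarises ages, sex ratio and ethnicity", {
  samples <- tibble::tibble(
    sample_id = c("A", "B", "C", "D"),
    diagnosis = c("PD", "PD", "PD", "PD"),
    age = c(60, 80, 70, 70), sex = c("M", "M", "M", "F"),
    ethnicity = c("Caucasian", "Caucasian", "Caucasian", "Other"))
  d <- demographics_table(samples)
  total <- d[d$diagnosis == "Total", ]
  expect_equal(total$mean_age, 70.0)
  expect_equal(total$min_age, 60)
  expect_equal(total$max_age, 80)
  expect_equal(total$male_female, "3.0:1.0")
  expect_equal(total$pct_caucasian, 75.0)

  males <- dplyr::mutate(samples, sex = "M")
  expect_equal(demographics_table(males)$male_female[1], "all male")
  expect_error(demographics_table(samples[0, ]),
               class = "neuropanel_empty_cohort")
})

test_that("yield table reproduces the published total row from per-stratum fixtures", {
  x <- yield_fixture()
  yt <- yield_table(x[, c("sample_id", "n_variants")],
                    x[, c("sample_id", "diagnosis")])
  total <- yt[yt$diagnosis == "Total", ]
  expect_equal(total$n, 216)
  expect_equal(total$n_without, 60)
  expect_equal(total$pct_without, 27.8)
  expect_equal(total$n_with, 156)
  expect_equal(total$pct_with, 72.2)
  expect_equal(total$n_with_1, 76)
  expect_equal(total$pct_with_1, 48.7)
  expect_equal(total$n_with_2, 57)
  expect_equal(total$pct_with_2, 36.5)
  expect_equal(total$n_with_ge3, 23)
  # 23/156 recomputes to 14.7 at one decimal; the count is authoritative
  expect_equal(total$pct_with_ge3, 14.7)
  # row conservation and per-stratum sums to total
  expect_true(all(yt$n_without + yt$n_with == yt$n))
  expect_true(all(yt$n_with_1 + yt$n_with_2 + yt$n_with_ge3 == yt$n_with))
  strata <- yt[yt$diagnosis != "Total", ]
  for (col in c("n", "n_without", "n_with", "n_with_1", "n_with_2",
                "n_with_ge3")) {
    expect_equal(sum(strata[[col]]), total[[col]])
  }
})

test_that("yield table handles single-sample edge cases", {
  one <- tibble::tibble(sample_id = "A", diagnosis = "PD")
  y0 <- yield_table(tibble::tibble(sample_id = "A", n_variants = 0L), one)
  expect_equal(y0$n_without[1], 1)
  expect_equal(y0$pct_without[1], 100.0)
  y5 <- yield_table(tibble::tibble(sample_id = "A", n_variants = 5L), one)
  expect_equal(y5$n_with_ge3[1], 1)
})

test_that("variant-origin table reproduces the published total row", {
  fx <- origin_fixture()
  vo <- variant_origin_table(fx$classified, fx$samples)
  total <- vo[vo$diagnosis == "Total", ]
  expect_equal(total$n_variants, 266)
  expect_equal(total$n_with_variants, 156)
  expect_equal(total$n_in_diagnosed_gene, 107)
  expect_equal(total$pct_in_diagnosed_gene, 40.2)
  expect_equal(total$n_in_other_panel_gene, 159)
  expect_equal(total$pct_in_other_panel_gene, 59.8)
  expect_equal(total$n_in_disease_db, 62)
  expect_equal(total$pct_in_disease_db, 23.3)
  expect_equal(total$n_not_in_disease_db, 204)
  expect_equal(total$pct_not_in_disease_db, 76.7)
  expect_true(all(vo$n_in_diagnosed_gene + vo$n_in_other_panel_gene ==
                    vo$n_variants))
  expect_true(all(vo$n_in_disease_db + vo$n_not_in_disease_db ==
                    vo$n_variants))
  strata <- vo[vo$diagnosis != "Total", ]
  for (col in c("n_variants", "n_in_diagnosed_gene", "n_in_disease_db")) {
    expect_equal(sum(strata[[col]]), total[[col]])
  }
})

test_that("variant-origin table edge cases", {
  samples <- tibble::tibble(sample_id = "A", diagnosis = "AD_MCI")
  one <- tibble::tibble(sample_id = "A", category = "clinically_relevant",
                        concordant_gene = TRUE, in_hgmd = FALSE,
                        in_clinvar = TRUE, recurrent_artifact = FALSE)
  vo <- variant_origin_table(one, samples)
  expect_equal(vo$n_variants[1], 1)
  expect_equal(vo$pct_in_diagnosed_gene[1], 100.0)
  expect_equal(vo$n_not_in_disease_db[1], 0)

  vo0 <- variant_origin_table(one[0, ], samples)
  expect_equal(vo0$n_variants[1], 0)
})

test_that("other-risk table reproduces published C9orf72 and APOE percentages", {
  spec <- tibble::tibble(
    diagnosis = c("AD_MCI", "ALS", "FTD", "PD", "VCI"),
    n = c(40, 22, 21, 56, 77),
    c9 = c(0, 2, 1, 0, 0),
    e2e3 = c(1, 4, 1, 10, 10), e2e4 = c(0, 0, 0, 1, 0),
    e3e3 = c(17, 12, 13, 39, 50), e3e4 = c(15, 6, 5, 5, 14),
    e4e4 = c(7, 0, 2, 1, 3))
  rows <- purrr::pmap(spec, function(diagnosis, n, c9, e2e3, e2e4, e3e3,
                                     e3e4, e4e4) {
    tibble::tibble(
      diagnosis = diagnosis,
      c9orf72_expansion = seq_len(n) <= c9,
      apoe = rep(c("E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4"),
                 c(e2e3, e2e4, e3e3, e3e4, e4e4)))
  })
  x <- dplyr::bind_rows(rows)
  x$sample_id <- sprintf("S%03d", seq_len(nrow(x)))
  tab <- other_risk_table(x[, c("sample_id", "diagnosis",
                                "c9orf72_expansion")], x$apoe)
  total <- tab[tab$diagnosis == "Total", ]
  expect_equal(total$n, 216)
  expect_equal(total$n_c9orf72, 3)
  expect_equal(total$pct_c9orf72, 1.39)  # 3/216 recomputed
  expect_equal(total$n_e3e3, 131L)
  expect_equal(total$pct_e3e3, 60.6)
  expect_equal(total$pct_e4e4, 6.02)
  expect_equal(total$pct_e2e4, 0.46)
  als <- tab[tab$diagnosis == "ALS", ]
  expect_equal(als$n_c9orf72, 2)
  expect_equal(als$pct_c9orf72, 9.09)
  pd <- tab[tab$diagnosis == "PD", ]
  expect_equal(pd$pct_e2e3, 17.9)
  # no carriers
  none <- dplyr::mutate(x, c9orf72_expansion = FALSE)
  tab0 <- other_risk_table(none[, c("sample_id", "diagnosis",
                                    "c9orf72_expansion")], x$apoe)
  expect_equal(tab0$pct_c9orf72[1], 0)
})

test_that("Sanger amplicon estimate uses ceiling division", {
  expect_equal(estimate_sanger_amplicons(971388, 500), 1943L)
  expect_equal(estimate_sanger_amplicons(500, 500), 1L)
  expect_equal(estimate_sanger_amplicons(501, 500), 2L)
  expect_error(estimate_sanger_amplicons(971388, 0),
               class = "neuropanel_bad_input")
})
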