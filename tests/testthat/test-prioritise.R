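test_that("rarity rule: every present database MAF must be below threshold", {
  cfg <- prioritisation_config()
  expect_true(is_rare(NA, NA, 0.00006, cfg))
  expect_false(is_rare(0.05, NA, NA, cfg))
  expect_true(is_rare(NA, NA, NA, cfg))
  expect_false(is_rare(0.005, 0.02, 0.001, cfg))
  # exac_only variant of the rule ignores the other databases
  cfg2 <- prioritisation_config(rarity_rule = "exac_only")
  expect_true(is_rare(0.05, NA, 0.001, cfg2))
  expect_false(is_rare(NA, NA, 0.02, cfg2))
})

test_that("config files in YAML and JSON round-trip into prioritisation_config", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("maf_threshold: 0.005", "rarity_rule: exac_only",
               "cadd_scale: raw"), y)
  cfg <- read_prioritisation_config(y)
  expect_equal(cfg$maf_threshold, 0.005)
  expect_equal(cfg$rarity_rule, "exac_only")
  expect_equal(cfg$cadd_cutoff, 0)  # raw-scale default

  j <- tempfile(fileext = ".json")
  writeLines('{"maf_threshold": 0.02, "artifact_cohort_fraction": 0.2}', j)
  cfgj <- read_prioritisation_config(j)
  expect_equal(cfgj$maf_threshold, 0.02)
  expect_equal(cfgj$artifact_cohort_fraction, 0.2)

  bad <- tempfile(fileext = ".yaml")
  writeLines("not_a_field: 1", bad)
  expect_error(read_prioritisation_config(bad),
               class = "neuropanel_bad_config")
})

test_that("qualifying consequences are the five deleterious classes", {
  expect_true(all(qualifying_consequence(
    c("missense", "nonsense", "frameshift", "inframe_indel", "splicing"))))
  expect_false(any(qualifying_consequence(c("synonymous", "noncoding"))))
  expect_error(qualifying_consequence("intergenicish"),
               class = "neuropanel_bad_consequence")
})

test_that("predicted_damaging matches the full rule table over all predictor combinations", {
  cfg <- prioritisation_config()  # phred scale, cutoff 20
  pp_levels <- c("benign", "possibly_damaging", "probably_damaging",
                 NA_character_)
  sift_levels <- c("tolerated", "deleterious", NA_character_)
  cadd_levels <- c(1, 25, NA_real_)
  for (pp in pp_levels) for (sf in sift_levels) for (cd in cadd_levels) {
    support <- isTRUE(pp %in% c("possibly_damaging", "probably_damaging")) ||
      isTRUE(sf == "deleterious")
    veto <- !is.na(cd) && cd < 20
    expected <- if (is.na(pp) && is.na(sf) && is.na(cd)) "unknown"
    else if (support && !veto) "true" else "false"
    expect_identical(predicted_damaging(pp, sf, cd, cfg), expected,
                     label = sprintf("pp=%s sift=%s cadd=%s", pp, sf, cd))
  }
  expect_identical(
    predicted_damaging("probably_damaging", "deleterious", 25, cfg), "true")
  expect_identical(predicted_damaging("benign", "tolerated", 1, cfg), "false")
})

test_that("classify_variants matches the brute-force rule oracle on the full grid", {
  cfg <- prioritisation_config()
  grid <- expand.grid(
    gene = c("APP", "NOT_A_PANEL_GENE"),
    rare = c(TRUE, FALSE),
    consequence = c("missense", "nonsense", "frameshift", "inframe_indel",
                    "splicing", "synonymous"),
    in_hgmd = c(TRUE, FALSE),
    in_clinvar = c(TRUE, FALSE),
    damaging = c("true", "false", "unknown"),
    stringsAsFactors = FALSE)
  samples <- tibble::tibble(sample_id = "S1", diagnosis = "AD_MCI")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pred <- switch(g$damaging,
      true = list(pp = "probably_damaging", sf = "deleterious", cadd = 30),
      false = list(pp = "benign", sf = "tolerated", cadd = NA_real_),
      unknown = list(pp = NA_character_, sf = NA_character_,
                     cadd = NA_real_))
    av <- make_av(gene = g$gene, consequence = g$consequence,
                  maf_exac = if (g$rare) 0.001 else 0.05,
                  polyphen = pred$pp, sift = pred$sf, cadd = pred$cadd,
                  in_hgmd = g$in_hgmd, in_clinvar = g$in_clinvar)
    got <- classify_variants(av, samples, the_panel, cfg)$category
    expected <- oracle_classify(
      on_panel = g$gene == "APP", rare = g$rare,
      qualifying = g$consequence != "synonymous",
      in_db = g$in_hgmd || g$in_clinvar, damaging = g$damaging)
    expect_identical(got, expected,
                     label = paste(unlist(g), collapse = " "))
  }
})

test_that("classification is pure and exclusion reasons name the failed filter", {
  cfg <- prioritisation_config()
  samples <- tibble::tibble(sample_id = "S1", diagnosis = "VCI")
  av <- make_av(gene = "SOD1", consequence = "missense", maf_1000g = 0.05)
  r1 <- classify_variants(av, samples, the_panel, cfg)
  r2 <- classify_variants(av, samples, the_panel, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$category, "excluded")
  expect_match(r1$reason_codes, "NOT_RARE")

  # rare damaging novel variant in an ALS gene carried by a VCI patient
  av2 <- make_av(gene = "SOD1", consequence = "missense", maf_exac = 1e-4,
                 polyphen = "probably_damaging", sift = "deleterious",
                 cadd = 30)
  r3 <- classify_variants(av2, samples, the_panel, cfg)
  expect_equal(r3$category, "uncertain_significance")
  expect_false(r3$concordant_gene)
})

test_that("lowering the MAF threshold never rescues an excluded variant", {
  samples <- tibble::tibble(sample_id = "S1", diagnosis = "PD")
  mafs <- c(0.0005, 0.002, 0.008, 0.015, 0.05)
  for (m in mafs) {
    av <- make_av(gene = "LRRK2", consequence = "missense", maf_exac = m)
    hi <- classify_variants(av, samples, the_panel,
                            prioritisation_config(maf_threshold = 0.01))
    lo <- classify_variants(av, samples, the_panel,
                            prioritisation_config(maf_threshold = 0.001))
    if (hi$category == "excluded") expect_equal(lo$category, "excluded")
  }
})

test_that("recurrent-artifact flagging uses the cohort carrier fraction", {
  cfg <- prioritisation_config(artifact_cohort_fraction = 0.10)
  samples <- tibble::tibble(sample_id = sprintf("S%03d", 1:216),
                            diagnosis = rep("PD", 216))
  one <- classify_variants(
    make_av(sample_id = "S001", gene = "LRRK2", consequence = "missense",
            maf_exac = 1e-4),
    samples, the_panel, cfg)
  one <- flag_recurrent_artifacts(one, 216, cfg)
  expect_false(one$recurrent_artifact)

  many <- dplyr::bind_rows(lapply(sprintf("S%03d", 1:40), function(s) {
    make_av(sample_id = s, gene = "LRRK2", consequence = "missense",
            maf_exac = 1e-4)
  }))
  cl <- classify_variants(many, samples, the_panel, cfg)
  cl <- flag_recurrent_artifacts(cl, 216, cfg)
  expect_true(all(cl$recurrent_artifact))       # 40/216 > 0.10
  expect_equal(unique(cl$shared_in_diagnosis), 40L)

  solo <- flag_recurrent_artifacts(one, 1, cfg)  # cohort of one: 1/1 > 0.10
  expect_true(solo$recurrent_artifact)
})

test_that("per-sample counts skip excluded variants and bins partition the cohort", {
  # high artifact cutoff: a 3-sample cohort should not trip the flag
  cfg <- prioritisation_config(artifact_cohort_fraction = 0.5)
  samples <- tibble::tibble(sample_id = c("A", "B", "C"),
                            diagnosis = c("PD", "PD", "VCI"))
  av <- dplyr::bind_rows(
    make_av(sample_id = "A", gene = "LRRK2", consequence = "missense",
            maf_exac = 0.05),                       # excluded
    make_av(sample_id = "A", gene = "SNCA", pos = 2000L,
            consequence = "missense", maf_exac = 1e-4))  # uncertain
  cl <- flag_recurrent_artifacts(
    classify_variants(av, samples, the_panel, cfg), 3, cfg)
  out <- count_variants_per_sample(cl, samples$sample_id)
  expect_equal(out$counts$n_variants, c(1L, 0L, 0L))
  expect_equal(out$distribution$n, c(2L, 1L, 0L, 0L))
  expect_equal(sum(out$distribution$n), 3)

  empty <- count_variants_per_sample(cl[0, ], character(0))
  expect_equal(nrow(empty$counts), 0)
  expect_equal(sum(empty$distribution$n), 0)
})

test_that("simulated carrier rate is recovered within a 95% binomial interval", {
  cfg <- simulation_config(n_samples = 216, carrier_rate = 0.722,
                           seed = 11L)
  b <- simulate_cohort(cfg)
  observed <- sum(b$truth_samples$intended_n_qualifying > 0)
  ci <- stats::binom.test(observed, 216, p = 0.722)$conf.int
  expect_true(ci[1] <= 0.722 && 0.722 <= ci[2])
})
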