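#' Seeded synthetic cohorts
#'
#' Generates a cohort with the statistical structure the analysis assumes:
#' diagnosis strata apportioned by largest remainder, per-sample variant
#' calls in panel genes with known intended classifications, an annotation
#' resource keyed to those calls, APOE SNP genotypes drawn under
#' Hardy-Weinberg equilibrium, C9orf72 expansion flags, run-QC inputs and
#' perturbed platform replicates. One global seed expands into fixed named
#' sub-streams (metadata, APOE, variants, QC, replicates) so adding a
#' generator never perturbs existing streams.
#'
#' @name synthetic_data
NULL

STREAM_OFFSETS <- c(metadata = 101L, apoe = 202L, variants = 303L,
                    qc = 404L, replicates = 505L)

stream_seed <- function(config, stream) {
  (config$seed + STREAM_OFFSETS[[stream]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Defaults mirror the printed cohort facts of the study the panel was
#' designed for: 216 samples split 40/22/21/56/77 across AD/MCI, ALS, FTD,
#' PD and VCI; 72.2% of samples carrying at least one qualifying variant,
#' split 48.7/36.5/14.8 across the 1/2/3+ bins; 23.3% of qualifying
#' variants in a disease database; 40.2% in a gene concordant with the
#' carrier's diagnosis; APOE allele frequencies 0.0625/0.7708/0.1667
#' (E2/E3/E4); a 3-in-216 C9orf72 expansion rate (drawn among ALS/FTD
#' samples); mean target coverage 76x.
#'
#' @param n_samples Cohort size.
#' @param diagnosis_proportions Named fractions summing to 1 over the five
#'   diagnoses.
#' @param carrier_rate Fraction of samples with >= 1 qualifying variant.
#' @param variants_per_carrier Named probabilities over bins `1`, `2`,
#'   `3+` for the carrier's qualifying-variant count.
#' @param damaging_rate Probability a qualifying variant carries
#'   supportive in-silico predictions.
#' @param db_membership_rate Probability a qualifying variant is in HGMD
#'   or ClinVar.
#' @param concordant_gene_rate Probability a qualifying variant falls in a
#'   gene of the carrier's own disease category.
#' @param rare_maf_max Upper bound of the simulated rare-variant MAF range.
#' @param decoy_rate Mean number (Poisson) of non-qualifying decoy
#'   variants (common or synonymous) per sample.
#' @param apoe_allele_freqs Named fractions over E2/E3/E4 summing to 1.
#' @param c9_carrier_rate Expected overall C9orf72 expansion-carrier rate.
#' @param mean_coverage Mean per-base target depth for QC simulation.
#' @param replicate_discordance Genotype-flip fraction for simulated
#'   platform replicates.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples = 216,
    diagnosis_proportions = c(AD_MCI = 0.185, ALS = 0.102, FTD = 0.098,
                              PD = 0.259, VCI = 0.356),
    carrier_rate = 156 / 216,
    variants_per_carrier = c(`1` = 76 / 156, `2` = 57 / 156,
                             `3+` = 23 / 156),
    damaging_rate = 0.75,
    db_membership_rate = 62 / 266,
    concordant_gene_rate = 107 / 266,
    rare_maf_max = 0.005,
    decoy_rate = 1.5,
    apoe_allele_freqs = c(E2 = 27 / 432, E3 = 333 / 432, E4 = 72 / 432),
    c9_carrier_rate = 3 / 216,
    mean_coverage = 76,
    replicate_discordance = 0,
    seed = 1L) {
  fr <- c(carrier_rate, damaging_rate, db_membership_rate,
          concordant_gene_rate, c9_carrier_rate, replicate_discordance)
  if (any(fr < 0 | fr > 1)) {
    stop_input("rates must lie in [0, 1]", "neuropanel_bad_config")
  }
  if (n_samples < 1) {
    stop_input("n_samples must be >= 1", "neuropanel_bad_config")
  }
  if (abs(sum(diagnosis_proportions) - 1) > 1e-6) {
    stop_input("diagnosis_proportions must sum to 1", "neuropanel_bad_config")
  }
  if (!setequal(names(diagnosis_proportions), DIAGNOSES)) {
    stop_input("diagnosis_proportions must name the five diagnoses",
               "neuropanel_bad_config")
  }
  if (abs(sum(apoe_allele_freqs) - 1) > 1e-6 ||
      !setequal(names(apoe_allele_freqs), c("E2", "E3", "E4"))) {
    stop_input("apoe_allele_freqs must name E2/E3/E4 and sum to 1",
               "neuropanel_bad_config")
  }
  if (abs(sum(variants_per_carrier) - 1) > 1e-6 ||
      !setequal(names(variants_per_carrier), c("1", "2", "3+"))) {
    stop_input("variants_per_carrier must name bins 1, 2, 3+ and sum to 1",
               "neuropanel_bad_config")
  }
  if (mean_coverage <= 0) {
    stop_input("mean_coverage must be positive", "neuropanel_bad_config")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Largest-remainder apportionment of stratum sizes
#'
#' Deterministic: floors each quota, then distributes the leftover units
#' to the largest fractional remainders (ties broken by the given order).
#'
#' @param n Total count.
#' @param proportions Named fractions summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
apportion_strata <- function(n, proportions) {
  quota <- n * proportions
  sizes <- floor(quota)
  left <- n - sum(sizes)
  if (left > 0) {
    order_rem <- order(quota - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(left)]] <- sizes[order_rem[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(sizes), names(proportions))
}

# Table-1-style age and sex parameters per diagnosis
AGE_PARAMS <- list(
  AD_MCI = c(74.5, 6.6), ALS = c(61.9, 9.1), FTD = c(68.8, 6.6),
  PD = c(68.0, 5.9), VCI = c(70.2, 7.4))
MALE_PROB <- c(AD_MCI = 24 / 40, ALS = 12 / 22, FTD = 10 / 21,
               PD = 43 / 56, VCI = 51 / 77)

APOE_ALLELE_TO_SNPS <- list(E2 = c("T", "T"), E3 = c("T", "C"),
                            E4 = c("C", "C"))

#' Simulate a synthetic cohort bundle
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, the bundle is written there
#'   (`metadata.tsv`, `annotations.tsv`, `truth_variants.tsv`,
#'   `truth_samples.tsv` and one `vcf/<sample_id>.vcf` per sample).
#' @param panel Panel definition used for gene and coordinate placement.
#' @return List: `samples` (metadata tibble, including the two APOE SNP
#'   genotypes), `calls`, `annotations`, `truth_variants` (per-variant
#'   intended category), `truth_samples` (per-sample intended qualifying
#'   count), `apoe_truth` (the generating diplotypes).
#' @export
simulate_cohort <- function(config = simulation_config(), dir = NULL,
                            panel = load_panel()) {
  stopifnot(inherits(config, "simulation_config"))
  sizes <- apportion_strata(config$n_samples, config$diagnosis_proportions)
  diagnosis <- rep(names(sizes), sizes)
  ids <- sprintf("S%04d", seq_len(config$n_samples))

  samples <- withr::with_seed(stream_seed(config, "metadata"), {
    age <- vapply(diagnosis, function(d) {
      p <- AGE_PARAMS[[d]]
      max(40, min(90, round(rnorm(1, p[1], p[2]))))
    }, numeric(1))
    sex <- ifelse(runif(length(ids)) < MALE_PROB[diagnosis], "M", "F")
    eth <- ifelse(runif(length(ids)) < 0.823, "Caucasian", "Other")
    fam <- runif(length(ids)) < 0.05
    alsftd <- diagnosis %in% c("ALS", "FTD")
    c9rate <- if (any(alsftd)) {
      min(1, config$c9_carrier_rate * length(ids) / sum(alsftd))
    } else config$c9_carrier_rate
    c9 <- runif(length(ids)) < c9rate & (alsftd | !any(alsftd))
    tibble(sample_id = ids, diagnosis = diagnosis, age = age, sex = sex,
           ethnicity = eth, family_history = fam, c9orf72_expansion = c9)
  })

  apoe <- withr::with_seed(stream_seed(config, "apoe"), {
    f <- config$apoe_allele_freqs
    a1 <- sample(names(f), config$n_samples, replace = TRUE, prob = f)
    a2 <- sample(names(f), config$n_samples, replace = TRUE, prob = f)
    dip <- mapply(function(x, y) paste(sort(c(x, y)), collapse = "/"),
                  a1, a2)
    gt112 <- mapply(function(x, y) {
      paste(sort(c(APOE_ALLELE_TO_SNPS[[x]][1], APOE_ALLELE_TO_SNPS[[y]][1])),
            collapse = "/")
    }, a1, a2)
    gt158 <- mapply(function(x, y) {
      paste(sort(c(APOE_ALLELE_TO_SNPS[[x]][2], APOE_ALLELE_TO_SNPS[[y]][2])),
            collapse = "/")
    }, a1, a2)
    tibble(sample_id = ids, apoe_genotype = unname(dip),
           gt_rs429358 = unname(gt112), gt_rs7412 = unname(gt158))
  })
  samples$gt_rs429358 <- apoe$gt_rs429358
  samples$gt_rs7412 <- apoe$gt_rs7412

  vb <- withr::with_seed(stream_seed(config, "variants"),
                         simulate_variants(config, samples, panel))

  bundle <- list(samples = samples, calls = vb$calls,
                 annotations = vb$annotations,
                 truth_variants = vb$truth_variants,
                 truth_samples = vb$truth_samples,
                 apoe_truth = apoe)
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

# Internal: per-sample variant and annotation generation (one RNG stream).
simulate_variants <- function(config, samples, panel) {
  genes <- panel$genes
  targets <- panel$targets
  gene_counter <- stats::setNames(rep(0L, nrow(genes)), genes$symbol)
  bases <- c("A", "C", "G", "T")
  bins <- c(1L, 2L, 3L, 4L)
  bin_prob <- c(config$variants_per_carrier[["1"]],
                config$variants_per_carrier[["2"]],
                config$variants_per_carrier[["3+"]] * 0.75,
                config$variants_per_carrier[["3+"]] * 0.25)

  new_site <- function(gene) {
    gene_counter[gene] <<- gene_counter[gene] + 1L
    t <- targets[targets$symbol == gene, ]
    pos <- t$start + 1L + (gene_counter[gene] - 1L) * 11L
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    list(chrom = t$chrom, pos = as.integer(pos), ref = ref, alt = alt)
  }

  call_rows <- list()
  ann_rows <- list()
  truth_rows <- list()
  intended_n <- integer(nrow(samples))

  maybe <- function(p, value) if (runif(1) < p) value else NA

  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    diag <- samples$diagnosis[i]
    cat_ <- diagnosis_category(diag)
    carrier <- runif(1) < config$carrier_rate
    k <- if (carrier) sample(bins, 1, prob = bin_prob) else 0L
    intended_n[i] <- k
    own_genes <- genes$symbol[genes$disease_category == cat_]
    other_genes <- setdiff(genes$symbol, own_genes)

    for (j in seq_len(k)) {
      concord <- runif(1) < config$concordant_gene_rate
      gene <- if (concord) sample(own_genes, 1) else sample(other_genes, 1)
      site <- new_site(gene)
      damaging <- runif(1) < config$damaging_rate
      in_db <- runif(1) < config$db_membership_rate
      if (damaging) {
        pp <- sample(c("probably_damaging", "possibly_damaging"), 1,
                     prob = c(0.7, 0.3))
        sf <- sample(c("deleterious", "tolerated"), 1, prob = c(0.8, 0.2))
        cadd <- maybe(0.8, round(runif(1, 21, 40), 3))
      } else {
        pp <- "benign"
        sf <- "tolerated"
        cadd <- maybe(0.8, round(runif(1, 0.5, 15), 3))
      }
      cons <- sample(QUALIFYING_CONSEQUENCES, 1,
                     prob = c(0.7, 0.08, 0.08, 0.06, 0.08))
      all_absent <- runif(1) < 0.2
      maf_exac <- if (all_absent) NA else
        signif(runif(1, 1e-6, config$rare_maf_max), 3)
      maf_1000g <- if (all_absent) NA else
        maybe(0.5, signif(runif(1, 1e-6, config$rare_maf_max), 3))
      maf_esp <- if (all_absent) NA else
        maybe(0.5, signif(runif(1, 1e-6, config$rare_maf_max), 3))
      gt_hom <- runif(1) < 0.08
      genotype <- if (gt_hom) paste(site$alt, site$alt, sep = "/")
      else paste(site$ref, site$alt, sep = "/")
      depth <- rpois(1, config$mean_coverage)
      intended <- if (in_db && damaging) "clinically_relevant"
      else "uncertain_significance"
      call_rows[[length(call_rows) + 1]] <- tibble(
        sample_id = sid, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, genotype = genotype,
        depth = depth)
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        chrom = site$chrom, pos = site$pos, ref = site$ref,
        alt = site$alt, gene = gene, consequence = cons,
        maf_1000g = as.numeric(maf_1000g), maf_esp = as.numeric(maf_esp),
        maf_exac = as.numeric(maf_exac), polyphen = pp, sift = sf,
        cadd = as.numeric(cadd), in_hgmd = in_db,
        in_clinvar = in_db & runif(1) < 0.6,
        hgvs_c = NA_character_, hgvs_p = NA_character_)
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        sample_id = sid, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, gene = gene,
        intended_category = intended, intended_concordant = concord)
    }

    n_decoy <- rpois(1, config$decoy_rate)
    for (j in seq_len(n_decoy)) {
      gene <- sample(genes$symbol, 1)
      site <- new_site(gene)
      common <- runif(1) < 0.5
      if (common) {
        cons <- "missense"
        maf_1000g <- signif(runif(1, 0.02, 0.3), 3)
        reason <- "NOT_RARE"
      } else {
        cons <- sample(c("synonymous", "noncoding"), 1)
        maf_1000g <- maybe(0.5, signif(runif(1, 1e-6, config$rare_maf_max), 3))
        reason <- "NOT_QUALIFYING_CONSEQUENCE"
      }
      call_rows[[length(call_rows) + 1]] <- tibble(
        sample_id = sid, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt,
        genotype = paste(site$ref, site$alt, sep = "/"),
        depth = rpois(1, config$mean_coverage))
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        chrom = site$chrom, pos = site$pos, ref = site$ref,
        alt = site$alt, gene = gene, consequence = cons,
        maf_1000g = as.numeric(maf_1000g), maf_esp = NA_real_,
        maf_exac = NA_real_,
        polyphen = NA_character_, sift = NA_character_, cadd = NA_real_,
        in_hgmd = FALSE, in_clinvar = FALSE,
        hgvs_c = NA_character_, hgvs_p = NA_character_)
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        sample_id = sid, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, gene = gene,
        intended_category = "excluded", intended_concordant = NA)
    }
  }

  calls <- bind_rows(call_rows)
  annotations <- bind_rows(ann_rows)
  if (nrow(annotations) > 0) {
    key <- paste(annotations$chrom, annotations$pos, annotations$ref,
                 annotations$alt)
    annotations <- annotations[!duplicated(key), ]
  } else {
    annotations <- empty_annotation_table()
  }
  list(calls = calls, annotations = annotations,
       truth_variants = bind_rows(truth_rows),
       truth_samples = tibble(sample_id = samples$sample_id,
                              intended_n_qualifying = intended_n))
}

empty_annotation_table <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), gene = character(), consequence = character(),
         maf_1000g = numeric(), maf_esp = numeric(), maf_exac = numeric(),
         polyphen = character(), sift = character(), cadd = numeric(),
         in_hgmd = logical(), in_clinvar = logical(),
         hgvs_c = character(), hgvs_p = character())
}

#' Write a sample's calls as a VCF 4.2 file
#'
#' @param calls Call tibble for one sample.
#' @param path Output path.
#' @param sample_id Sample column name; default taken from the calls.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(calls, path, sample_id = NULL) {
  sample_id <- sample_id %||% unique(calls$sample_id)[1] %||% "sample"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neuropanel_simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
    gt_idx <- ifelse(calls$genotype == paste(calls$alt, calls$alt, sep = "/"),
                     "1/1", "0/1")
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", ".", "GT:DP",
                  paste0(gt_idx, ":", calls$depth), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$samples, file.path(dir, "metadata.tsv"),
                   na = ".", progress = FALSE)
  write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(bundle$truth_variants,
                   file.path(dir, "truth_variants.tsv"), na = ".",
                   progress = FALSE)
  readr::write_tsv(bundle$truth_samples,
                   file.path(dir, "truth_samples.tsv"), na = ".",
                   progress = FALSE)
  for (sid in bundle$samples$sample_id) {
    write_sample_vcf(bundle$calls[bundle$calls$sample_id == sid, ],
                     file.path(dir, "vcf", paste0(sid, ".vcf")),
                     sample_id = sid)
  }
  invisible(dir)
}

#' Simulate run-QC input
#'
#' Per-base depths are negative-binomial around the configured mean
#' (moderate overdispersion, emulating amplicon-capture coverage
#' heterogeneity); read totals follow the run-sheet magnitudes and respect
#' the count invariants.
#'
#' @param config A [simulation_config()].
#' @param target_bp Target length in bases (default the full panel size).
#' @param scale Down-scaling factor for the depth vector length (tests use
#'   small fractions).
#' @return A [run_qc_input()].
#' @export
simulate_run_qc <- function(config = simulation_config(),
                            target_bp = 971388, scale = 1) {
  stopifnot(config$mean_coverage > 0, scale > 0)
  withr::with_seed(stream_seed(config, "qc"), {
    n <- max(1L, as.integer(round(target_bp * scale)))
    depths <- rnbinom(n, size = 8, mu = config$mean_coverage)
    total <- round(rnorm(1, 29.8e6, 2.5e6))
    pf <- round(total * runif(1, 0.70, 0.85))
    mapped <- round(pf * runif(1, 0.90, 0.96))
    q30 <- round(mapped * runif(1, 0.85, 0.92))
    run_qc_input(total_reads = total, reads_pf = pf,
                 mapped_reads = mapped, reads_ge_q30 = q30,
                 per_base_depths = depths,
                 cluster_density = round(rnorm(1, 1433.6, 165), 1))
  })
}

#' Simulate a perturbed platform replicate
#'
#' Flips genotypes (het to hom-alt and vice versa) at a
#' Bernoulli(`discordance`) subset of calls, recording which rows flipped.
#'
#' @param calls Truth call tibble.
#' @param discordance Flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return `calls` with perturbed `genotype` and a logical `flipped`
#'   column.
#' @export
simulate_replicate_callset <- function(calls, discordance, seed = 1L) {
  stopifnot(discordance >= 0, discordance <= 1)
  withr::with_seed(seed, {
    flip <- runif(nrow(calls)) < discordance
    het <- paste(calls$ref, calls$alt, sep = "/")
    hom <- paste(calls$alt, calls$alt, sep = "/")
    out <- calls
    out$genotype <- ifelse(flip,
                           ifelse(calls$genotype == het, hom, het),
                           calls$genotype)
    out$flipped <- flip
    out
  })
}
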