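# Synthetic cohort generator: configuration, planted truth, read counts,
# blacklists and gene models.

test_that("configuration is validated", {
  expect_error(cohort_config(organs_per_individual = character(0)),
               "configuration error")
  expect_error(cohort_config(organs_per_individual = "spleen"), "organ")
  expect_error(cohort_config(early_rate = -1), "rates")
  expect_error(cohort_config(seq_error_rate = 0), "seq_error_rate")
})

test_that("empty cohort yields no truth records but valid schemas", {
  cfg <- fast_config(n_individuals = 4, early_rate = 0,
                     late_rate_by_organ = c(brain = 0, heart = 0,
                                            liver = 0, other = 0),
                     blood_intercept = 0, blood_slope = 0,
                     tumor_fraction = 0, oxog_rate = 0,
                     n_blacklist_artifacts = 0, n_noise_sites = 5)
  co <- simulate_cohort(cfg)
  expect_equal(sum(!co$truth$artifact), 0)
  expect_equal(nrow(co$truth_vaf), 0)
  # noise sites still observed in every tissue
  expect_equal(nrow(co$observations), 4 * 3 * 5)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- fast_config(n_individuals = 3, seed = 11L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(fast_config(n_individuals = 3, seed = 12L))
  expect_false(identical(co1$observations, co3$observations))
})

test_that("early mutations share site and clone VAF across all tissues", {
  co <- shared_cohort()
  early <- co$truth[co$truth$stage == "early" & !co$truth$artifact, ]
  skip_if(nrow(early) == 0, "no early mutations drawn in shared cohort")
  key <- paste(co$truth_vaf$individual, co$truth_vaf$pos)
  for (i in seq_len(nrow(early))) {
    rows <- co$truth_vaf[key == paste(early$individual[i], early$pos[i]), ]
    n_tissues <- sum(co$tissues$individual == early$individual[i])
    expect_equal(nrow(rows), n_tissues)
    expect_equal(length(unique(rows$vaf)), 1L)
    expect_gte(length(unique(
      co$tissues$organ[match(rows$tissue_id, co$tissues$tissue_id)])), 2)
  }
})

test_that("late mutations are confined to one organ; tumor to the tumor specimen", {
  co <- shared_cohort()
  tvkey <- paste(co$truth_vaf$individual, co$truth_vaf$pos)
  late <- co$truth[co$truth$stage == "late", ]
  for (i in seq_len(nrow(late))) {
    rows <- co$truth_vaf[tvkey == paste(late$individual[i], late$pos[i]), ]
    organs <- co$tissues$organ[match(rows$tissue_id, co$tissues$tissue_id)]
    expect_equal(unique(organs), late$organ[i])
    expect_equal(nrow(rows), 1L)
  }
  tum <- co$truth[co$truth$stage == "tumor", ]
  for (i in seq_len(nrow(tum))) {
    rows <- co$truth_vaf[tvkey == paste(tum$individual[i], tum$pos[i]), ]
    expect_true(all(co$tissues$is_tumor[match(rows$tissue_id,
                                              co$tissues$tissue_id)]))
  }
  # conservation: every carrier (truth, tissue) pair has an observation
  okey <- paste(co$observations$individual, co$observations$tissue_id,
                co$observations$pos)
  expect_true(all(paste(co$truth_vaf$individual, co$truth_vaf$tissue_id,
                        co$truth_vaf$pos) %in% okey))
})

test_that("blood late-mutation burden rises with age (n = 200)", {
  cfg <- fast_config(
    n_individuals = 200, early_rate = 0,
    late_rate_by_organ = c(brain = 0, heart = 0, liver = 0, other = 0),
    tumor_fraction = 0, oxog_rate = 0, n_blacklist_artifacts = 0,
    n_noise_sites = 0, seed = 303L)
  co <- simulate_cohort(cfg)
  counts <- table(factor(co$truth$individual[co$truth$stage == "late"],
                         levels = unique(co$tissues$individual)))
  ages <- co$tissues$age[match(names(counts), co$tissues$individual)]
  # independent recomputation of the correlation from the truth table
  r <- sum((ages - mean(ages)) * (counts - mean(counts))) /
    sqrt(sum((ages - mean(ages))^2) * sum((counts - mean(counts))^2))
  expect_gt(r, 0.3)
})

test_that("early mutation totals follow the configured Poisson rate", {
  cfg <- fast_config(
    n_individuals = 190, early_rate = 2,
    late_rate_by_organ = c(brain = 0, heart = 0, liver = 0, other = 0),
    blood_intercept = 0, blood_slope = 0, tumor_fraction = 0,
    oxog_rate = 0, n_blacklist_artifacts = 0, n_noise_sites = 0,
    seed = 404L)
  co <- simulate_cohort(cfg)
  n_early <- sum(co$truth$stage == "early")
  expect_lt(abs(n_early - 380), 3 * sqrt(380))
})

test_that("planted per-stage VAF means match the truncated-normal means", {
  co <- simulate_cohort(fast_config(n_individuals = 40, seed = 505L))
  tkey <- paste(co$truth$individual, co$truth$pos)
  vkey <- paste(co$truth_vaf$individual, co$truth_vaf$pos)
  stage <- co$truth$stage[match(vkey, tkey)]
  for (st in c("early", "late")) {
    v <- co$truth_vaf$vaf[stage == st]
    # per-site (not per-tissue) VAFs for early to avoid duplication
    if (st == "early") {
      v <- tapply(co$truth_vaf$vaf[stage == st], vkey[stage == st], mean)
    }
    p <- co$config$vaf_params[[st]]
    expected <- truncnorm_mean(p[["mean"]], p[["sd"]])
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - expected), 3 * se + 1e-12)
  }
})

test_that("read-count simulation follows the binomial model", {
  expect_error(simulate_read_counts(0.1, 0, 1e-3), "depth")
  set.seed(1)
  expect_equal(simulate_read_counts(0, 500, 0)$alt_count, 0)
  one <- simulate_read_counts(1, 500, 0)
  expect_equal(one$alt_count, 500)
  expect_equal(one$vaf, 1)
  set.seed(2)
  rc <- simulate_read_counts(rep(0.0617, 10000), 500, 0)
  expect_lt(abs(mean(rc$vaf) - 0.0617) / 0.0617, 0.01)
  # with sequencing error the binomial expectation shifts accordingly
  set.seed(3)
  rc_e <- simulate_read_counts(rep(0.0617, 10000), 500, 1e-3)
  p_exp <- 0.0617 + 1e-3 * (1 - 0.0617)
  expect_lt(abs(mean(rc_e$vaf) - p_exp) / p_exp, 0.01)
  # orientation split is balanced for genuine variants
  expect_lt(abs(sum(rc$alt_f1r2) / sum(rc$alt_count) - 0.5), 0.01)
  # oxoG artifacts put >= 90% of alt reads on one orientation
  set.seed(4)
  ox <- simulate_read_counts(rep(0.05, 200), 500, 0, oxog = TRUE,
                             ref = "C")
  frac <- ox$alt_f2r1 / pmax(ox$alt_count, 1)
  expect_true(all(frac[ox$alt_count > 0] >= 0.9))
  ox_g <- simulate_read_counts(rep(0.05, 200), 500, 0, oxog = TRUE,
                               ref = "G")
  frac_g <- ox_g$alt_f1r2 / pmax(ox_g$alt_count, 1)
  expect_true(all(frac_g[ox_g$alt_count > 0] >= 0.9))
})

test_that("blacklists cover the configured fraction and are disjoint", {
  cfg <- cohort_config(n_individuals = 1, genome_size = 1e7,
                       fraction_blacklisted = 0.05, seed = 9L)
  bl <- generate_blacklists(cfg)
  expect_setequal(names(bl), c("common_snp", "segdup", "simple_repeat",
                               "low_mappability", "off_target", "utr"))
  total <- sum(vapply(bl, function(b) sum(b$end - b$start), numeric(1)))
  expect_lt(abs(total / 1e7 - 0.05) / 0.05, 0.02)
  all_iv <- do.call(rbind, bl)
  expect_false(any(duplicated(all_iv$start)))
  # zero fraction -> all tracks empty
  bl0 <- generate_blacklists(fast_config(fraction_blacklisted = 0))
  expect_true(all(vapply(bl0, nrow, integer(1)) == 0))
})

test_that("blacklist-planted artifacts appear in the expected-filtered manifest", {
  co <- shared_cohort()
  skip_if(nrow(co$expected_filtered) == 0)
  pos <- blacklist_positions <- unlist(lapply(co$blacklists, function(b) {
    unlist(Map(seq, b$start + 1L, b$end))
  }))
  expect_true(all(co$expected_filtered$pos %in% pos))
  expect_true(all(paste(co$expected_filtered$individual,
                        co$expected_filtered$pos) %in%
                    paste(co$truth$individual[co$truth$artifact],
                          co$truth$pos[co$truth$artifact])))
})

test_that("gene models are translatable coding sequences", {
  co <- shared_cohort()
  genes <- co$genes
  expect_true(all((genes$end - genes$start + 1L) %% 3 == 0))
  # independent translation oracle via Biostrings
  for (i in sample(nrow(genes), 5)) {
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(genes$cds_seq[i]), if.fuzzy.codon = "X"))
    expect_identical(prot, genes$protein[i])
  }
  expect_true(all(co$pli$pli >= 0 & co$pli$pli <= 1))
  expect_true(all(abs(colSums(co$ref_signatures) - 1) < 1e-9))
})

test_that("truth context channels match the genome sequence", {
  co <- shared_cohort()
  tr <- co$truth[!co$truth$artifact, ]
  up <- substring(co$genome$seq, tr$pos - 1L, tr$pos - 1L)
  down <- substring(co$genome$seq, tr$pos + 1L, tr$pos + 1L)
  ref <- substring(co$genome$seq, tr$pos, tr$pos)
  expect_identical(ref, tr$ref)
  expect_identical(classify_context(tr$ref, tr$alt, up, down), tr$channel)
})
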