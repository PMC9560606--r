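# End-to-end pipeline driver, descriptive summaries and the validation
# harness against the generator's truth tables.

#' Per-group descriptive summaries
#'
#' Summarizes classified variants per stage (and late-stage variants per
#' organ): counts, per-individual rates (raw and tissue-normalized), VAF
#' mean and sd, and Pearson correlations of age with per-individual counts
#' and VAFs (exact two-sided p via the t transform, as in
#' [stats::cor.test()]). Degenerate groups (no variants, or zero variance)
#' are flagged with NA.
#'
#' @param classified classified-variant table from [classify_stage()].
#' @param tissues cohort tissue metadata.
#' @return data.frame with one row per group.
#' @export
summarize_groups <- function(classified, tissues) {
  meta <- unique(tissues[, c("individual", "age")])
  n_tissue <- table(tissues$individual)
  tumor_ind <- unique(tissues$individual[tissues$is_tumor])
  groups <- list()
  for (st in STAGE_LABELS) {
    groups[[st]] <- classified[classified$stage == st, , drop = FALSE]
  }
  late <- classified[classified$stage == "late", , drop = FALSE]
  for (org in unique(late$organs)) {
    groups[[paste0("late_", org)]] <- late[late$organs == org, ,
                                           drop = FALSE]
  }
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    eligible <- if (g == "tumor") tumor_ind else meta$individual
    if (startsWith(g, "late_")) {
      org <- sub("^late_", "", g)
      eligible <- unique(tissues$individual[tissues$organ == org &
                                              !tissues$is_tumor])
    }
    counts <- vapply(eligible, function(id) {
      sum(v$individual == id)
    }, numeric(1))
    norm <- if (length(eligible) > 0) {
      normalize_counts(counts, as.numeric(n_tissue[eligible]))
    } else numeric(0)
    ages <- meta$age[match(eligible, meta$individual)]
    ct_count <- safe_cor(ages, counts)
    vaf_ind <- vapply(eligible, function(id) {
      mean(v$mean_vaf[v$individual == id])
    }, numeric(1))
    has_vaf <- !is.na(vaf_ind)
    ct_vaf <- safe_cor(ages[has_vaf], vaf_ind[has_vaf])
    data.frame(
      group = g, n_variants = nrow(v),
      per_individual = if (length(counts)) mean(counts) else NA_real_,
      per_individual_norm = if (length(norm)) mean(norm) else NA_real_,
      vaf_mean = if (nrow(v)) mean(v$mean_vaf) else NA_real_,
      vaf_sd = if (nrow(v) > 1) stats::sd(v$mean_vaf) else NA_real_,
      age_count_r = ct_count$r, age_count_p = ct_count$p,
      age_vaf_r = ct_vaf$r, age_vaf_p = ct_vaf$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pearson r with exact two-sided p via the t transform; NA-flagged when
# undefined (fewer than 3 points or zero variance).
safe_cor <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0 ||
      anyNA(x) || anyNA(y)) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Precision as a percentage
#'
#' The validation-report formula: `100 * n_confirmed / n_tested`.
#'
#' @param n_confirmed,n_tested confirmation counts.
#' @return percentage.
#' @export
#' @examples
#' validation_precision(17, 19)  # 89.47368...
validation_precision <- function(n_confirmed, n_tested) {
  if (any(n_tested <= 0)) stop("n_tested must be > 0")
  100 * n_confirmed / n_tested
}

#' Compare classified variants with the generator truth table
#'
#' Joins on (individual, contig, pos, ref, alt); per stage reports the
#' number tested (classified), confirmed (truth stage matches) and
#' precision, plus recall against all planted mutations of that stage and
#' the Pearson correlation between pipeline mean VAF and true mean clone
#' VAF over confirmed variants.
#'
#' @param classified classified-variant table.
#' @param truth truth table of the same cohort.
#' @param truth_vaf long true clone-VAF table.
#' @return list with `per_stage` data.frame and `vaf_concordance_r`.
#' @export
validate_against_truth <- function(classified, truth, truth_vaf) {
  tkey <- paste(truth$individual, truth$contig, truth$pos, truth$ref,
                truth$alt)
  ckey <- paste(classified$individual, classified$contig, classified$pos,
                classified$ref, classified$alt)
  truth_stage <- truth$stage[match(ckey, tkey)]
  truth_stage[is.na(truth_stage)] <- "none"
  per_stage <- do.call(rbind, lapply(STAGE_LABELS, function(st) {
    called <- classified$stage == st
    n_tested <- sum(called)
    n_confirmed <- sum(called & truth_stage == st)
    n_truth <- sum(truth$stage == st)
    data.frame(stage = st, n_tested = n_tested, n_confirmed = n_confirmed,
               precision = if (n_tested > 0)
                 validation_precision(n_confirmed, n_tested) / 100
                 else NA_real_,
               n_truth = n_truth,
               recall = if (n_truth > 0) n_confirmed / n_truth
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # VAF concordance over confirmed variants
  tv_key <- paste(truth_vaf$individual, truth_vaf$contig, truth_vaf$pos,
                  truth_vaf$ref, truth_vaf$alt)
  true_mean_vaf <- vapply(ckey, function(k) {
    v <- truth_vaf$vaf[tv_key == k]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1), USE.NAMES = FALSE)
  ok <- !is.na(true_mean_vaf)
  r <- if (sum(ok) >= 3) safe_cor(classified$mean_vaf[ok],
                                  true_mean_vaf[ok])$r else NA_real_
  list(per_stage = per_stage, vaf_concordance_r = r)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> reciprocal all-pairs calling -> presence decisions ->
#' filter cascade -> stage classification -> per-group summaries ->
#' signature analysis (96-channel catalogs per stage, de novo NMF,
#' reference refitting, strand asymmetry, exposure clustering) ->
#' selection statistics (dN/dS, atypical mutability, pLI) -> validation
#' against truth. Pure function of `config`; with `out_dir` set, every
#' stage's tables are persisted as TSV/VCF/BED alongside a JSON run log.
#'
#' @param config a [cohort_config()].
#' @param params a [caller_params()] list.
#' @param nmf_rank signatures to extract de novo (default 3).
#' @param nmf_restarts NMF restarts for the pipeline run (default 10).
#' @param out_dir optional output directory.
#' @return list with cohort, candidates, classified, summaries, signatures,
#'   selection and validation components.
#' @export
run_pipeline <- function(config, params = caller_params(), nmf_rank = 3,
                         nmf_restarts = 10, out_dir = NULL) {
  cohort <- simulate_cohort(config)
  cand_list <- lapply(split(cohort$tissues, cohort$tissues$individual),
                      function(tis) {
    if (nrow(tis) < 2) return(NULL)
    obs <- cohort$observations[cohort$observations$individual ==
                                 tis$individual[1], ]
    all_pairs_call(tis, obs, params)$candidates
  })
  candidates <- do.call(rbind, c(unname(cand_list),
                                 list(all_pairs_empty_agg())))
  presence <- presence_decisions(cohort$observations, params)
  cls <- classify_stage(candidates, presence, cohort$tissues, params,
                        cohort$blacklists)
  classified <- cls$variants
  summaries <- summarize_groups(classified, cohort$tissues)

  # ---- signatures ----
  ckey <- paste(classified$contig, classified$pos)
  snv <- classified[nchar(classified$ref) == 1 & nchar(classified$alt) == 1, ]
  catalogs <- vapply(STAGE_LABELS, function(st) {
    build_catalog(snv[snv$stage == st, ], cohort$genome)
  }, numeric(96))
  signatures <- NULL
  refit <- NULL
  if (sum(catalogs) > 0 && nmf_rank <= ncol(catalogs)) {
    signatures <- extract_signatures_nmf(catalogs, rank = nmf_rank,
                                         n_restarts = nmf_restarts,
                                         seed = config$seed)
    refit <- lapply(STAGE_LABELS, function(st) {
      refit_exposures(catalogs[, st], cohort$ref_signatures)
    })
    names(refit) <- STAGE_LABELS
  }
  tkey <- paste(cohort$truth$individual, cohort$truth$contig,
                cohort$truth$pos, cohort$truth$ref, cohort$truth$alt)
  skey <- paste(snv$individual, snv$contig, snv$pos, snv$ref, snv$alt)
  snv$tx_strand <- cohort$truth$tx_strand[match(skey, tkey)]
  asym <- lapply(STAGE_LABELS, function(st) {
    strand_asymmetry(snv[snv$stage == st, ])
  })
  names(asym) <- STAGE_LABELS

  # ---- selection ----
  model <- build_coding_model(cohort$genes, cohort$genome)
  ann <- annotate_consequence(snv, model, cohort$genome)
  selection <- lapply(STAGE_LABELS, function(st) {
    dnds_mle(ann[ann$stage == st, ], model)
  })
  names(selection) <- STAGE_LABELS
  chan <- cohort$truth$channel[match(skey, tkey)]
  atypical <- lapply(STAGE_LABELS, function(st) {
    atypical_mutability(chan[snv$stage == st])
  })
  names(atypical) <- STAGE_LABELS
  pli <- pli_profile(split(ann$gene_id, ann$stage), cohort$pli)

  validation <- validate_against_truth(classified, cohort$truth,
                                       cohort$truth_vaf)
  out <- list(cohort = cohort, candidates = candidates,
              classified = classified, verdicts = cls$verdicts,
              per_tissue = cls$per_tissue, summaries = summaries,
              catalogs = catalogs, signatures = signatures, refit = refit,
              strand_asymmetry = asym, selection = selection,
              atypical = atypical, pli = pli, validation = validation)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

all_pairs_empty_agg <- function() {
  cbind(empty_candidates()[, c("individual", "contig", "pos", "ref", "alt",
                               "case_tissue")],
        data.frame(n_controls = integer(0), controls = character(0),
                   pass_primary = logical(0), pass_secondary = logical(0)))
}
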