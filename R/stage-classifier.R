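# Post-call filter cascade and early/late/tumor stage assignment.
#
# Early = presence in >= 2 distinct organs (tumor specimens never count
# toward the organ tally); late = presence in exactly one non-tumor organ;
# tumor = presence only in a tumor specimen. Shared variants that are
# invisible to the case/control contrast are rescued through the
# concordance track.

#' Read-orientation oxoG artifact filter
#'
#' 8-oxoguanine damage produces C>A/G>T calls whose alternate reads sit
#' almost entirely on one read orientation (F2R1 for C>A, F1R2 for G>T).
#' An observation fails when the artifact-prone orientation carries >= 90%
#' of the alternate reads and the alternate count is <= 20; all other
#' substitution types always pass.
#'
#' @param ref,alt reference and alternate bases (vectorized).
#' @param alt_f1r2,alt_f2r1 orientation-split alternate read counts.
#' @return logical vector, `TRUE` = keep.
#' @export
#' @examples
#' oxog_filter("C", "A", 0, 10)  # FALSE: all reads on artifact orientation
#' oxog_filter("C", "A", 5, 5)   # TRUE
oxog_filter <- function(ref, alt, alt_f1r2, alt_f2r1) {
  n_alt <- alt_f1r2 + alt_f2r1
  prone <- ifelse(ref == "C" & alt == "A", alt_f2r1,
                  ifelse(ref == "G" & alt == "T", alt_f1r2, NA_real_))
  frac <- prone / pmax(n_alt, 1L)
  keep <- is.na(prone) | n_alt == 0 | !(frac >= 0.9 & n_alt <= 20)
  as.logical(keep)
}

# Convert a blacklist data.frame (0-based half-open) to GRanges.
blacklist_granges <- function(b) {
  if (nrow(b) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(b$contig,
                         IRanges::IRanges(start = b$start + 1L, end = b$end))
}

#' Apply the BED blacklist cascade to a set of sites
#'
#' A site fails a track iff its position lies within any interval of that
#' track (intervals are 0-based half-open, so a site at the `end`
#' coordinate passes). The verdict records every track independently; the
#' final `keep` is the conjunction of all tracks passing.
#'
#' @param sites data.frame with columns `contig` and `pos` (1-based).
#' @param blacklists named list of BED data.frames (columns contig, start,
#'   end) as produced by [generate_blacklists()] or [read_bed()].
#' @return data.frame of per-track logical pass columns plus `keep`.
#' @export
region_filters <- function(sites, blacklists) {
  n <- nrow(sites)
  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos, sites$pos))
  verdict <- data.frame(row.names = seq_len(max(n, 0)))
  for (track in names(blacklists)) {
    hits <- GenomicRanges::countOverlaps(gr, blacklist_granges(
      blacklists[[track]]))
    verdict[[track]] <- hits == 0
  }
  verdict$keep <- Reduce(`&`, verdict, rep(TRUE, n))
  verdict
}

#' Concordance test for multi-organ shared candidates
#'
#' A shared candidate seen at VAF `vaf_a` in an anchor tissue is confirmed
#' in a partner tissue when (i) the partner's alternate count is consistent
#' with the anchor VAF under a two-sided exact binomial test (p >= alpha)
#' and (ii) the partner's presence test rejects background error. This
#' rescues shared variants that the case/control contrast cannot see.
#'
#' @param alt_b,depth_b partner-tissue alternate and total read counts.
#' @param vaf_a anchor-tissue VAF, strictly inside (0, 1).
#' @param error_rate background error for the presence test.
#' @param alpha significance level for both parts.
#' @return list with `concordant`, `p_concordance`, `p_presence`.
#' @export
#' @examples
#' shared_concordance_test(30, 500, 0.06)$concordant   # TRUE
#' shared_concordance_test(150, 500, 0.06)$concordant  # FALSE
shared_concordance_test <- function(alt_b, depth_b, vaf_a,
                                    error_rate = 1e-3, alpha = 0.05) {
  if (any(vaf_a <= 0 | vaf_a >= 1)) {
    stop("vaf_a must be strictly inside (0, 1)")
  }
  p_conc <- vapply(seq_along(alt_b), function(i) {
    v <- if (length(vaf_a) > 1) vaf_a[i] else vaf_a
    d <- if (length(depth_b) > 1) depth_b[i] else depth_b
    binom_two_sided(alt_b[i], d, v)
  }, numeric(1))
  p_pres <- presence_test(alt_b, depth_b, error_rate)
  list(concordant = p_conc >= alpha & p_pres < alpha,
       p_concordance = p_conc, p_presence = p_pres)
}

#' Per-tissue presence decisions
#'
#' Presence of a variant in a tissue is an exact binomial presence test
#' against the background error, Benjamini-Hochberg adjusted within the
#' tissue across its sites.
#'
#' @param observations observation table (any number of tissues).
#' @param params a [caller_params()] list.
#' @return the observation table plus `p_presence`, `p_presence_adj` and
#'   logical `present`.
#' @export
presence_decisions <- function(observations, params = caller_params()) {
  if (nrow(observations) == 0) {
    observations$p_presence <- numeric(0)
    observations$p_presence_adj <- numeric(0)
    observations$present <- logical(0)
    return(observations)
  }
  p <- presence_test(observations$alt_count, observations$depth,
                     params$error_rate)
  padj <- unsplit(lapply(split(p, observations$tissue_id),
                         stats::p.adjust, method = "BH"),
                  observations$tissue_id)
  observations$p_presence <- p
  observations$p_presence_adj <- padj
  observations$present <- padj <= params$alpha_call
  observations
}

#' Divide a mutation count by the number of tissues analyzed
#'
#' Per-individual mutation counts are normalized by the number of tissues
#' examined so that individuals with more sampled tissues are comparable.
#'
#' @param n_mutations,n_tissues counts; `n_tissues` >= 1.
#' @return `n_mutations / n_tissues`.
#' @export
normalize_counts <- function(n_mutations, n_tissues) {
  if (any(n_tissues < 1)) stop("n_tissues must be >= 1")
  n_mutations / n_tissues
}

# Rescue shared candidates invisible to the case/control contrast: sites
# present in >= 2 tissues with no candidate call anywhere, confirmed by the
# concordance track against the highest-VAF anchor tissue.
shared_rescue <- function(presence, candidates, params) {
  if (nrow(presence) == 0) return(presence[0, c("individual", "contig",
                                                "pos", "ref", "alt")])
  key <- paste(presence$individual, presence$contig, presence$pos,
               presence$ref, presence$alt)
  cand_key <- unique(paste(candidates$individual, candidates$contig,
                           candidates$pos, candidates$ref, candidates$alt))
  out <- list()
  for (k in unique(key[presence$present])) {
    if (k %in% cand_key) next
    rows <- presence[key == k & presence$present, ]
    if (nrow(rows) < 2) next
    # any present tissue may serve as the anchor of the matched pair
    for (a in seq_len(nrow(rows))) {
      anchor <- rows[a, ]
      if (anchor$vaf <= 0 || anchor$vaf >= 1) next
      partners <- rows[-a, ]
      conc <- shared_concordance_test(partners$alt_count, partners$depth,
                                      anchor$vaf, params$error_rate,
                                      params$alpha_ctrl)
      if (any(conc$concordant)) {
        out[[k]] <- rows[1, c("individual", "contig", "pos", "ref", "alt")]
        break
      }
    }
  }
  if (length(out) == 0) {
    return(presence[0, c("individual", "contig", "pos", "ref", "alt")])
  }
  do.call(rbind, out)
}

#' Classify candidate variants into early / late / tumor stages
#'
#' Takes the union of (a) all-pairs candidates with both ensemble passes
#' and (b) shared-concordance rescues, applies the oxoG and region filter
#' cascade, determines per-tissue presence, and assigns the stage from the
#' organ tally: tumor specimens never count toward the organ set, so
#' presence in a tumor specimen plus one organ is late, and presence only
#' in tumor specimens is tumor.
#'
#' @param candidates aggregated candidate table from [all_pairs_call()]
#'   (rows for several individuals may be concatenated).
#' @param presence output of [presence_decisions()] for the same cohort.
#' @param tissues tissue metadata (tissue_id, individual, organ, is_tumor).
#' @param params a [caller_params()] list.
#' @param blacklists optional named list of blacklist tracks.
#' @return list with `variants` (one row per classified variant: stage,
#'   organs, n_tissues_present, mean VAF over presence tissues),
#'   `verdicts` (per-variant filter outcomes for all considered variants)
#'   and `per_tissue` (long presence detail for classified variants).
#' @export
classify_stage <- function(candidates, presence, tissues,
                           params = caller_params(), blacklists = NULL) {
  if (!all(tissues$organ %in% ORGAN_LABELS)) {
    stop("unknown organ label(s): ",
         paste(setdiff(tissues$organ, ORGAN_LABELS), collapse = ", "))
  }
  strict <- candidates[candidates$pass_primary & candidates$pass_secondary, ,
                       drop = FALSE]
  rescued <- shared_rescue(presence, candidates, params)
  uni <- unique(rbind(
    strict[, c("individual", "contig", "pos", "ref", "alt")],
    rescued))
  empty <- data.frame(
    individual = character(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), stage = character(0),
    organs = character(0), n_tissues_present = integer(0),
    mean_vaf = numeric(0), stringsAsFactors = FALSE)
  if (nrow(uni) == 0) {
    return(list(variants = empty, verdicts = cbind(uni, keep = logical(0)),
                per_tissue = presence[0, ]))
  }
  rownames(uni) <- NULL

  # ---- filter cascade (site level) ----
  pres_key <- paste(presence$individual, presence$contig, presence$pos,
                    presence$ref, presence$alt)
  uni_key <- paste(uni$individual, uni$contig, uni$pos, uni$ref, uni$alt)
  # oxoG: a site fails when every alt-bearing observation fails the
  # orientation filter.
  oxog_keep <- vapply(uni_key, function(k) {
    rows <- presence[pres_key == k & presence$alt_count > 0, ]
    if (nrow(rows) == 0) return(TRUE)
    any(oxog_filter(rows$ref, rows$alt, rows$alt_f1r2, rows$alt_f2r1))
  }, logical(1), USE.NAMES = FALSE)
  verdict <- data.frame(uni, oxog = oxog_keep, stringsAsFactors = FALSE)
  if (!is.null(blacklists)) {
    verdict <- cbind(verdict, region_filters(uni, blacklists))
    verdict$keep <- NULL
  }
  track_cols <- setdiff(names(verdict), names(uni))
  verdict$keep <- Reduce(`&`, verdict[track_cols], rep(TRUE, nrow(uni)))

  kept <- uni[verdict$keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(variants = empty, verdicts = verdict,
                per_tissue = presence[0, ]))
  }

  # ---- stage assignment ----
  tumor_ids <- tissues$tissue_id[tissues$is_tumor]
  kept_key <- paste(kept$individual, kept$contig, kept$pos, kept$ref,
                    kept$alt)
  res <- lapply(seq_len(nrow(kept)), function(i) {
    rows <- presence[pres_key == kept_key[i] & presence$present, ]
    if (nrow(rows) == 0) return(NULL)
    organs <- unique(tissues$organ[match(
      setdiff(rows$tissue_id, tumor_ids), tissues$tissue_id)])
    stage <- if (length(organs) >= 2) "early"
             else if (length(organs) == 1) "late"
             else "tumor"
    data.frame(kept[i, ], stage = stage,
               organs = paste(sort(organs), collapse = ","),
               n_tissues_present = nrow(rows),
               mean_vaf = mean(rows$vaf), stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, c(res, list(empty)))
  rownames(variants) <- NULL
  var_key <- paste(variants$individual, variants$contig, variants$pos,
                   variants$ref, variants$alt)
  list(variants = variants, verdicts = verdict,
       per_tissue = presence[pres_key %in% var_key & presence$present, ])
}
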