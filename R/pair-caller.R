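# Reciprocal all-pairs somatic candidate detection. The published caller
# ensemble is modeled as two independent pass flags on a defined read-count
# caller: pass_primary is the exact-binomial case/control contrast, and
# pass_secondary is a strand-balance + minimum-VAF heuristic standing in for
# the second caller's filter; downstream classification requires both.

#' Caller parameters
#'
#' @param error_rate assumed per-base substitution error (null proportion of
#'   the presence test).
#' @param alpha_call significance level for case presence after
#'   Benjamini-Hochberg adjustment across the tissue's sites.
#' @param alpha_ctrl level above which the control presence p-value is
#'   considered consistent with absence.
#' @param vaf_min,alt_min minimum case VAF and alternate read count.
#' @return named list of parameters.
#' @export
caller_params <- function(error_rate = 1e-3, alpha_call = 0.05,
                          alpha_ctrl = 0.05, vaf_min = 0.005, alt_min = 3) {
  list(error_rate = error_rate, alpha_call = alpha_call,
       alpha_ctrl = alpha_ctrl, vaf_min = vaf_min, alt_min = alt_min)
}

#' Exact one-sample binomial presence test
#'
#' Tests whether the alternate read count at a site exceeds what sequencing
#' error alone would produce. For `alternative = "greater"` returns the
#' exact upper tail P(X >= alt_count) under Binomial(depth, error_rate); no
#' normal approximation is used below depth 10 000 (nor above: the exact
#' tail is computed throughout). The two-sided alternative follows the
#' `binom.test` convention (sum of outcome probabilities not exceeding that
#' of the observation) and is used by the shared-mutation concordance test.
#'
#' @param alt_count,depth alternate and total read counts (vectorized).
#' @param error_rate null proportion, in (0, 1).
#' @param alternative "greater" (default) or "two.sided".
#' @return numeric vector of p-values.
#' @export
#' @examples
#' presence_test(5, 500, 1e-3)   # ~1.7e-4
#' presence_test(0, 500, 1e-3)   # 1
presence_test <- function(alt_count, depth, error_rate,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(depth <= 0)) stop("invalid input: depth must be > 0")
  if (error_rate <= 0 || error_rate >= 1) {
    stop("invalid input: error_rate must be in (0, 1)")
  }
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("invalid input: need 0 <= alt_count <= depth")
  }
  if (alternative == "greater") {
    stats::pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
  } else {
    binom_two_sided(alt_count, depth, error_rate)
  }
}

# Vectorized exact two-sided binomial p-value, binom.test convention.
binom_two_sided <- function(x, n, p) {
  vapply(seq_along(x), function(i) {
    ni <- if (length(n) > 1) n[i] else n
    d <- stats::dbinom(0:ni, ni, p)
    sum(d[d <= stats::dbinom(x[i], ni, p) * (1 + 1e-7)])
  }, numeric(1))
}

# Align two per-tissue observation tables on (contig, pos, ref, alt).
align_sites <- function(a, b) {
  key_a <- paste(a$contig, a$pos, a$ref, a$alt)
  key_b <- paste(b$contig, b$pos, b$ref, b$alt)
  idx <- match(key_a, key_b)
  if (anyNA(idx)) stop("case and control observations are not indexed ",
                       "on identical sites")
  idx
}

#' Call somatic candidates in a case tissue against one control tissue
#'
#' A site is emitted when (i) the case presence test rejects at
#' `alpha_call` after Benjamini-Hochberg adjustment across the case
#' tissue's sites, (ii) the control alternate support is consistent with
#' absence (control presence p-value > `alpha_ctrl`), and (iii) the case
#' VAF and alternate count clear `vaf_min` / `alt_min`. `pass_primary`
#' records (i) and (ii); `pass_secondary` is the independent
#' strand-balance + minimum-VAF heuristic.
#'
#' @param case_obs,control_obs observation data.frames for two tissues of
#'   the same individual (columns contig, pos, ref, alt, depth, alt_count,
#'   alt_f1r2, alt_f2r1, vaf, tissue_id, individual).
#' @param params a [caller_params()] list.
#' @return data.frame of candidate calls (possibly 0 rows).
#' @export
call_pair <- function(case_obs, control_obs, params = caller_params()) {
  if (nrow(case_obs) == 0) return(empty_candidates())
  if (length(unique(c(case_obs$individual, control_obs$individual))) != 1) {
    stop("case and control tissues must come from the same individual")
  }
  idx <- align_sites(case_obs, control_obs)
  ctl <- control_obs[idx, ]
  p_case <- presence_test(case_obs$alt_count, case_obs$depth,
                          params$error_rate)
  padj <- stats::p.adjust(p_case, method = "BH")
  p_ctrl <- presence_test(ctl$alt_count, ctl$depth, params$error_rate)
  keep <- padj <= params$alpha_call &
    p_ctrl > params$alpha_ctrl &
    case_obs$vaf >= params$vaf_min &
    case_obs$alt_count >= params$alt_min
  if (!any(keep)) return(empty_candidates())
  out <- data.frame(
    individual = case_obs$individual[keep],
    contig = case_obs$contig[keep], pos = case_obs$pos[keep],
    ref = case_obs$ref[keep], alt = case_obs$alt[keep],
    case_tissue = case_obs$tissue_id[keep],
    control_tissue = ctl$tissue_id[keep],
    case_alt = case_obs$alt_count[keep], case_depth = case_obs$depth[keep],
    case_vaf = case_obs$vaf[keep],
    p_case = p_case[keep], p_case_adj = padj[keep], p_control = p_ctrl[keep],
    pass_primary = TRUE,
    pass_secondary = secondary_pass(case_obs[keep, ], params),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Stand-in for the second caller's filter: minimum VAF plus a read
# orientation balance guard on modest alternate counts.
secondary_pass <- function(obs, params) {
  dominant <- pmax(obs$alt_f1r2, obs$alt_f2r1) /
    pmax(obs$alt_count, 1L)
  obs$alt_count >= params$alt_min &
    obs$vaf >= params$vaf_min &
    !(obs$alt_count <= 20 & dominant >= 0.95)
}

empty_candidates <- function() {
  data.frame(individual = character(0), contig = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             case_tissue = character(0), control_tissue = character(0),
             case_alt = integer(0), case_depth = integer(0),
             case_vaf = numeric(0), p_case = numeric(0),
             p_case_adj = numeric(0), p_control = numeric(0),
             pass_primary = logical(0), pass_secondary = logical(0),
             stringsAsFactors = FALSE)
}

#' Reciprocal all-pairs calling across one individual's tissues
#'
#' Runs [call_pair()] for every ordered pair of tissues; a tissue's
#' candidate set is the union over the controls under which it was called.
#'
#' @param tissues tissue metadata for one individual (tissue_id, organ,
#'   is_tumor).
#' @param observations observation table covering those tissues.
#' @param params a [caller_params()] list.
#' @return list with `pairs` (per ordered pair calls) and `candidates`
#'   (per site x case tissue, aggregated over controls: `n_controls`,
#'   `controls`, pass flags).
#' @export
all_pairs_call <- function(tissues, observations, params = caller_params()) {
  ids <- tissues$tissue_id
  if (length(ids) < 2) {
    stop("all-pairs calling requires >= 2 tissues; for a single tissue ",
         "use tumor-vs-normal mode with an external control")
  }
  obs_by <- split(observations, observations$tissue_id)
  pair_list <- list()
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      pair_list[[paste(a, b)]] <- call_pair(obs_by[[a]], obs_by[[b]], params)
    }
  }
  pairs <- do.call(rbind, c(pair_list, list(empty_candidates())))
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0) {
    cand <- cbind(empty_candidates()[, c("individual", "contig", "pos",
                                         "ref", "alt", "case_tissue")],
                  data.frame(n_controls = integer(0), controls = character(0),
                             pass_primary = logical(0),
                             pass_secondary = logical(0)))
    return(list(pairs = pairs, candidates = cand))
  }
  key <- paste(pairs$contig, pairs$pos, pairs$ref, pairs$alt,
               pairs$case_tissue)
  agg <- lapply(split(seq_len(nrow(pairs)), key), function(rows) {
    r1 <- pairs[rows[1], ]
    data.frame(individual = r1$individual, contig = r1$contig, pos = r1$pos,
               ref = r1$ref, alt = r1$alt, case_tissue = r1$case_tissue,
               n_controls = length(rows),
               controls = paste(sort(pairs$control_tissue[rows]),
                                collapse = ","),
               pass_primary = any(pairs$pass_primary[rows]),
               pass_secondary = any(pairs$pass_secondary[rows]),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, agg)
  cand <- cand[order(cand$case_tissue, cand$pos), ]
  rownames(cand) <- NULL
  list(pairs = pairs, candidates = cand)
}
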