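# Functional-impact statistics per mutation group: coding-consequence
# annotation on the packaged gene models, a maximum-likelihood global dN/dS
# with 192 strand-specific trinucleotide rate classes, atypical context
# mutability, and pLI profiles.

# The 192 strand-specific classes: coding-strand trinucleotide (64) x
# alternate base (3 per trinucleotide).
coding_classes <- function() {
  tri <- apply(expand.grid(BASES, BASES, BASES,
                           stringsAsFactors = FALSE)[, 3:1], 1, paste,
               collapse = "")
  out <- character(0)
  for (t in sort(tri)) {
    for (a in setdiff(BASES, substr(t, 2, 2))) {
      out <- c(out, paste0(t, ">", a))
    }
  }
  out
}

codon_table <- function() {
  aa <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(aa), names(aa))
}

#' Build the coding model (transcripts + mutational opportunity tensor)
#'
#' Enumerates, for every CDS position and every alternate base, whether the
#' substitution is synonymous or nonsynonymous under the standard codon
#' table, and accumulates these opportunities into the 192 strand-specific
#' trinucleotide substitution classes (trinucleotide read on the coding
#' strand, flanks taken from the genome in transcript orientation).
#'
#' @param genes gene-model data.frame from [generate_gene_models()].
#' @param genome genome list.
#' @return list of class `coding_model`: `genes`, `classes`, `opp_syn` and
#'   `opp_nonsyn` (named opportunity counts per class), `codon_table`.
#' @export
build_coding_model <- function(genes, genome) {
  classes <- coding_classes()
  opp_syn <- stats::setNames(numeric(length(classes)), classes)
  opp_nonsyn <- opp_syn
  ct <- codon_table()
  for (g in seq_len(nrow(genes))) {
    L <- genes$end[g] - genes$start[g] + 1L
    ext <- substring(genome$seq, genes$start[g] - 1L, genes$end[g] + 1L)
    if (genes$strand[g] == "-") ext <- revcomp(ext)
    cds <- substr(ext, 2L, L + 1L)
    chars <- strsplit(cds, "")[[1]]
    extc <- strsplit(ext, "")[[1]]
    codon_idx <- (seq_len(L) - 1L) %/% 3L
    codon_pos <- (seq_len(L) - 1L) %% 3L + 1L
    codons <- paste0(chars[codon_idx * 3L + 1L], chars[codon_idx * 3L + 2L],
                     chars[codon_idx * 3L + 3L])
    tri <- paste0(extc[seq_len(L)], chars, extc[seq_len(L) + 2L])
    for (a in BASES) {
      ok <- chars != a
      new_codon <- codons
      substr(new_codon, codon_pos, codon_pos) <- a
      syn <- ct[codons] == ct[new_codon]
      cls <- paste0(tri, ">", a)
      t_syn <- table(cls[ok & syn])
      t_non <- table(cls[ok & !syn])
      opp_syn[names(t_syn)] <- opp_syn[names(t_syn)] + as.numeric(t_syn)
      opp_nonsyn[names(t_non)] <- opp_nonsyn[names(t_non)] +
        as.numeric(t_non)
    }
  }
  structure(list(genes = genes, classes = classes, opp_syn = opp_syn,
                 opp_nonsyn = opp_nonsyn, codon_table = ct),
            class = "coding_model")
}

#' Annotate coding consequence of SNVs
#'
#' Locates each variant in the single-exon CDS models, substitutes the
#' codon (reverse-complementing for minus-strand transcripts) and
#' classifies the change as synonymous, missense, nonsense or noncoding.
#' Also reports the 192-level strand-specific class used by [dnds_mle()].
#'
#' @param variants data.frame with `pos`, `ref`, `alt` (single bases).
#' @param model a [build_coding_model()] result.
#' @param genome genome list.
#' @return the input plus `gene_id`, `consequence` and `class` columns.
#' @export
annotate_consequence <- function(variants, model, genome) {
  genes <- model$genes
  ct <- model$codon_table
  n <- nrow(variants)
  gene_id <- rep(NA_character_, n)
  consequence <- rep("noncoding", n)
  cls <- rep(NA_character_, n)
  if (n == 0) {
    return(cbind(variants, gene_id = character(0),
                 consequence = character(0), class = character(0)))
  }
  hit <- findInterval(variants$pos, genes$start)
  for (i in seq_len(n)) {
    g <- hit[i]
    if (g < 1 || variants$pos[i] > genes$end[g]) next
    gene_id[i] <- genes$gene_id[g]
    if (genes$strand[g] == "+") {
      off <- variants$pos[i] - genes$start[g]        # 0-based CDS offset
      ref_c <- variants$ref[i]; alt_c <- variants$alt[i]
      up <- genome_base(genome, variants$pos[i] - 1L)
      down <- genome_base(genome, variants$pos[i] + 1L)
    } else {
      off <- genes$end[g] - variants$pos[i]
      ref_c <- complement_base(variants$ref[i])
      alt_c <- complement_base(variants$alt[i])
      up <- complement_base(genome_base(genome, variants$pos[i] + 1L))
      down <- complement_base(genome_base(genome, variants$pos[i] - 1L))
    }
    cds <- genes$cds_seq[g]
    if (substr(cds, off + 1L, off + 1L) != ref_c) {
      stop("reference mismatch inside CDS of ", genes$gene_id[g])
    }
    ci <- off %/% 3L
    cp <- off %% 3L + 1L
    codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
    new_codon <- codon
    substr(new_codon, cp, cp) <- alt_c
    aa0 <- ct[codon]; aa1 <- ct[new_codon]
    consequence[i] <- if (aa0 == aa1) "synonymous"
      else if (aa1 == "*") "nonsense" else "missense"
    cls[i] <- paste0(up, ref_c, down, ">", alt_c)
  }
  out <- variants
  out$gene_id <- gene_id
  out$consequence <- consequence
  out$class <- cls
  out
}

# Profile log-likelihood of omega for the joint Poisson model
#   n_S,c ~ Pois(lambda_c O_S,c),  n_N,c ~ Pois(omega lambda_c O_N,c),
# with lambda_c profiled out analytically.
dnds_profile_loglik <- function(omega, nS, nN, OS, ON) {
  lam <- (nS + nN) / (OS + omega * ON)
  ok <- is.finite(lam) & lam > 0
  sum(nS[ok] * log(lam[ok] * OS[ok] + (nS[ok] == 0)) -
        lam[ok] * OS[ok]) +
    sum(nN[ok] * log(omega * lam[ok] * ON[ok] + (nN[ok] == 0)) -
          omega * lam[ok] * ON[ok])
}

#' Maximum-likelihood global dN/dS
#'
#' Estimates a single selection coefficient omega from annotated coding
#' variants under a Poisson model with one mutation-rate parameter per
#' strand-specific trinucleotide class (estimated jointly from synonymous
#' and nonsynonymous observations, profiled out of the likelihood), and a
#' 95% profile-likelihood confidence interval. Nonsense changes count as
#' nonsynonymous. With no synonymous observation omega is undefined and
#' the result is flagged.
#'
#' @param variants annotated variants ([annotate_consequence()] output or
#'   any data.frame with `consequence` and `class`).
#' @param model a [build_coding_model()] result.
#' @return list of class `selection_result`: `n_syn`, `n_nonsyn`, `E_syn`,
#'   `E_nonsyn` (rate-weighted expectations at the fitted rates), `omega`,
#'   `ci`, `flagged`.
#' @export
dnds_mle <- function(variants, model) {
  v <- variants[variants$consequence != "noncoding", , drop = FALSE]
  n_syn <- sum(v$consequence == "synonymous")
  n_nonsyn <- sum(v$consequence %in% c("missense", "nonsense"))
  if (n_syn == 0) {
    return(structure(list(n_syn = 0L, n_nonsyn = n_nonsyn, E_syn = NA_real_,
                          E_nonsyn = NA_real_, omega = NA_real_,
                          ci = c(NA_real_, NA_real_), flagged = TRUE),
                     class = "selection_result"))
  }
  cl <- model$classes
  nS <- as.numeric(table(factor(
    v$class[v$consequence == "synonymous"], levels = cl)))
  nN <- as.numeric(table(factor(
    v$class[v$consequence != "synonymous"], levels = cl)))
  OS <- as.numeric(model$opp_syn)
  ON <- as.numeric(model$opp_nonsyn)
  if (n_nonsyn == 0) {
    omega_hat <- 0
    ll_hat <- dnds_profile_loglik(0, nS, nN, OS, ON)
  } else {
    opt <- stats::optimize(function(lw) {
      -dnds_profile_loglik(exp(lw), nS, nN, OS, ON)
    }, interval = c(-10, 6))
    omega_hat <- exp(opt$minimum)
    ll_hat <- -opt$objective
  }
  dev <- function(om) 2 * (ll_hat - dnds_profile_loglik(om, nS, nN, OS, ON))
  crit <- stats::qchisq(0.95, 1)
  lo <- tryCatch(stats::uniroot(function(om) dev(om) - crit,
                                c(1e-9, max(omega_hat, 1e-8)))$root,
                 error = function(e) 0)
  hi <- tryCatch(stats::uniroot(function(om) dev(om) - crit,
                                c(max(omega_hat, 1e-8), 1e4))$root,
                 error = function(e) Inf)
  lam <- (nS + nN) / (OS + omega_hat * ON)
  lam[!is.finite(lam)] <- 0
  structure(list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                 E_syn = sum(lam * OS), E_nonsyn = sum(lam * ON),
                 omega = omega_hat, ci = c(lo, hi), flagged = FALSE),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$flagged) {
    cat("dN/dS undefined (no synonymous observations);",
        x$n_nonsyn, "nonsynonymous\n")
  } else {
    cat(sprintf("dN/dS omega = %.3f [%.3f, %.3f] (nS=%d, nN=%d)\n",
                x$omega, x$ci[1], x$ci[2], x$n_syn, x$n_nonsyn))
  }
  invisible(x)
}

#' Simulate coding mutations with a known selection coefficient
#'
#' Samples (class, consequence) pairs proportionally to the model's
#' mutational opportunity, with nonsynonymous opportunity down-weighted by
#' `suppression` (1 = neutral). Used as the known-truth generator for
#' calibrating [dnds_mle()].
#'
#' @param model a [build_coding_model()] result.
#' @param n number of mutations.
#' @param suppression multiplicative weight on nonsynonymous opportunity.
#' @param seed RNG seed.
#' @return data.frame with `class` and `consequence`.
#' @export
simulate_coding_mutations <- function(model, n, suppression = 1, seed = 1L) {
  set.seed(seed)
  cl <- model$classes
  w <- c(model$opp_syn, suppression * model$opp_nonsyn)
  type <- rep(c("synonymous", "missense"), each = length(cl))
  pick <- sample.int(length(w), n, replace = TRUE, prob = w)
  data.frame(class = rep(cl, 2)[pick], consequence = type[pick],
             stringsAsFactors = FALSE)
}

#' Default context-mutability model
#'
#' A per-channel mutability score derived from the packaged clock-like
#' spectra mixture; a stand-in for an external mutability table.
#'
#' @return named numeric vector over [sbs_channels()].
#' @export
default_mutability_model <- function() {
  sp <- generator_spectra()
  drop(sp %*% c(cpg_clock = 0.3, flat_clock = 0.5, tcn = 0.15, oxid = 0.05))
}

#' Fraction of variants at atypical-mutability contexts
#'
#' A variant is atypical when the mutability score of its context channel
#' is at or below the `threshold_quantile` of the background score
#' distribution, i.e. the site mutated despite a low expected mutation
#' rate (ties at the quantile count as atypical).
#'
#' @param channels channel names of the group's variants.
#' @param model named mutability score vector (default
#'   [default_mutability_model()]).
#' @param threshold_quantile low-mutability quantile (default 0.10).
#' @return list with `fraction`, `n`, `threshold`, `flagged` (empty group).
#' @export
atypical_mutability <- function(channels, model = default_mutability_model(),
                                threshold_quantile = 0.10) {
  channels <- channels[!is.na(channels)]
  thr <- stats::quantile(model, threshold_quantile, names = FALSE)
  if (length(channels) == 0) {
    return(list(fraction = NA_real_, n = 0L, threshold = thr,
                flagged = TRUE))
  }
  if (!all(channels %in% names(model))) stop("unknown channel(s)")
  list(fraction = mean(model[channels] <= thr), n = length(channels),
       threshold = thr, flagged = FALSE)
}

#' pLI profiles of mutated genes per group
#'
#' Collects per-gene pLI scores for the mutated genes of each group and
#' compares groups with two-sided Wilcoxon rank-sum tests.
#'
#' @param gene_ids_by_group named list of gene-id vectors (one per group).
#' @param pli_table data.frame with `gene_id` and `pli`.
#' @return list with `values` (per-group pLI multisets), `summary`
#'   (n, n_missing, median per group) and `tests` (pairwise rank-sum
#'   p-value matrix).
#' @export
pli_profile <- function(gene_ids_by_group, pli_table) {
  values <- lapply(gene_ids_by_group, function(g) {
    g <- g[!is.na(g)]
    pli_table$pli[match(g, pli_table$gene_id)]
  })
  summary <- data.frame(
    group = names(values),
    n = vapply(values, function(v) sum(!is.na(v)), integer(1)),
    n_missing = vapply(values, function(v) sum(is.na(v)), integer(1)),
    median = vapply(values, function(v) stats::median(v, na.rm = TRUE),
                    numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  values <- lapply(values, function(v) v[!is.na(v)])
  k <- length(values)
  tests <- matrix(NA_real_, k, k, dimnames = list(names(values),
                                                  names(values)))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (length(values[[i]]) > 0 && length(values[[j]]) > 0) {
          tests[i, j] <- tests[j, i] <- stats::wilcox.test(
            values[[i]], values[[j]], exact = FALSE)$p.value
        }
      }
    }
  }
  list(values = values, summary = summary, tests = tests)
}
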