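# Mutation-context catalogs, de novo NMF signature extraction, NNLS
# refitting against reference signatures, indel channels, transcriptional
# strand asymmetry, and exposure clustering.

#' Build a 96-channel mutation catalog
#'
#' Purine-reference substitutions are reverse-complemented into pyrimidine
#' space; the channel total equals the number of contributing SNVs.
#'
#' @param variants data.frame with `pos`, `ref`, `alt` (single bases) on
#'   the cohort contig.
#' @param genome genome list from a [simulate_cohort()] result (or any
#'   list with a `seq` character element).
#' @return named integer vector of length 96 ([sbs_channels()] order).
#' @export
build_catalog <- function(variants, genome) {
  ch <- sbs_channels()
  counts <- stats::setNames(integer(96), ch)
  if (nrow(variants) == 0) return(counts)
  refg <- genome_base(genome, variants$pos)
  if (!all(refg == variants$ref)) {
    stop("reference base mismatch at position(s): ",
         paste(utils::head(variants$pos[refg != variants$ref]),
               collapse = ", "))
  }
  up <- genome_base(genome, variants$pos - 1L)
  down <- genome_base(genome, variants$pos + 1L)
  chan <- classify_context(variants$ref, variants$alt, up, down)
  tab <- table(factor(chan, levels = ch))
  counts[] <- as.integer(tab)
  counts
}

#' Cosine similarity of two non-negative vectors
#'
#' @param u,v numeric vectors of equal length, not both zero.
#' @return `u . v / (|u| |v|)` in \[0, 1\] for non-negative input.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# Generalized Kullback-Leibler divergence D(X || Y).
kl_divergence <- function(x, y) {
  pos <- x > 0
  sum(x[pos] * log(x[pos] / y[pos])) - sum(x) + sum(y)
}

#' De novo signature extraction by NMF
#'
#' Multiplicative-update non-negative matrix factorization minimizing the
#' generalized Kullback-Leibler divergence (the standard objective for
#' count catalogs), run for `n_iter` iterations from `n_restarts` random
#' initializations; the restart with the lowest reconstruction error is
#' kept. Signature columns of W are normalized to sum to 1 with the
#' compensating scale absorbed into the exposures H.
#'
#' @param catalogs 96 x m matrix of channel counts (one column per group
#'   or sample).
#' @param rank number of signatures to extract.
#' @param n_iter multiplicative updates per restart (default 200).
#' @param n_restarts random restarts (default 50).
#' @param seed RNG seed.
#' @param init optional list with `W` and `H` starting matrices; when
#'   supplied a single deterministic run is performed (no restarts).
#' @return list of class `signature_set`: `W` (96 x rank), `H` (rank x m),
#'   `kl` (best reconstruction error), `restart_errors`, `objective`
#'   (per-iteration trace of the best restart).
#' @export
extract_signatures_nmf <- function(catalogs, rank, n_iter = 200,
                                   n_restarts = 50, seed = 1L,
                                   init = NULL) {
  X <- as.matrix(catalogs)
  if (rank > min(dim(X))) {
    stop("rank exceeds matrix dimension (", paste(dim(X), collapse = " x "),
         ")")
  }
  if (any(X < 0)) stop("catalog matrix must be non-negative")
  eps <- 1e-10
  best <- NULL
  if (!is.null(init)) n_restarts <- 1L
  errs <- numeric(n_restarts)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    if (is.null(init)) {
      W <- matrix(stats::runif(nrow(X) * rank, 0.1, 1), nrow(X), rank)
      H <- matrix(stats::runif(rank * ncol(X), 0.1, 1), rank, ncol(X))
    } else {
      W <- as.matrix(init$W)
      H <- as.matrix(init$H)
    }
    trace <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (X / WH)) / pmax(colSums(W), eps)
      WH <- W %*% H + eps
      W <- W * ((X / WH) %*% t(H)) / pmax(rep(rowSums(H), each = nrow(W)),
                                          eps)
      trace[it] <- kl_divergence(X, W %*% H + eps)
    }
    errs[r] <- trace[n_iter]
    if (is.null(best) || errs[r] < best$kl) {
      best <- list(W = W, H = H, kl = errs[r], objective = trace)
    }
  }
  s <- colSums(best$W)
  W <- sweep(best$W, 2, s, "/")
  H <- best$H * s
  colnames(W) <- rownames(H) <- paste0("S", seq_len(rank))
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  structure(list(W = W, H = H, kl = best$kl, restart_errors = errs,
                 objective = best$objective), class = "signature_set")
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||,
# x >= 0. Self-contained (no NNLS solver is available in the environment).
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Refit a catalog onto fixed reference signatures
#'
#' Non-negative least-squares decomposition of a 96-channel catalog onto
#' reference signature columns, followed by iterative pruning: signatures
#' whose relative contribution falls below `prune_threshold` are zeroed
#' and the remainder refit (deconstructSigs-style). Contributions sum to 1
#' over the retained signatures.
#'
#' @param catalog numeric vector of 96 channel counts.
#' @param ref_signatures 96 x k matrix with columns summing to 1.
#' @param prune_threshold minimum relative contribution (default 0.06).
#' @return list with `exposures` (mutation counts attributed to each
#'   reference), `contributions` (relative, summing to 1), `dropped`
#'   (pruned signature names) and logical `flagged` for degenerate input.
#' @export
refit_exposures <- function(catalog, ref_signatures, prune_threshold = 0.06) {
  stopifnot(length(catalog) == nrow(ref_signatures))
  if (any(abs(colSums(ref_signatures) - 1) > 1e-6)) {
    stop("reference signature columns must be normalized")
  }
  k <- ncol(ref_signatures)
  nm <- colnames(ref_signatures)
  if (sum(catalog) == 0) {
    return(list(exposures = stats::setNames(numeric(k), nm),
                contributions = stats::setNames(rep(NA_real_, k), nm),
                dropped = character(0), flagged = TRUE))
  }
  active <- rep(TRUE, k)
  repeat {
    x <- numeric(k)
    x[active] <- nnls_fit(as.matrix(ref_signatures[, active, drop = FALSE]),
                          catalog)
    contrib <- x / sum(x)
    weak <- active & contrib < prune_threshold
    if (!any(weak) || sum(active & !weak) == 0) break
    active <- active & !weak
  }
  list(exposures = stats::setNames(x, nm),
       contributions = stats::setNames(contrib, nm),
       dropped = nm[!active], flagged = FALSE)
}

INDEL_CHANNELS <- c("ins1_homshort", "ins1_homlong", "del1_homshort",
                    "del1_homlong", "ins_2plus", "del_2plus")

# Length of the homopolymer run of base `b` in the reference starting at
# 1-based position `from` (scanning right) plus any matching bases at
# from-1 scanning left.
homopolymer_run <- function(genome, from, b) {
  run <- 0L
  i <- from
  while (i <= genome$length && genome_base(genome, i) == b) {
    run <- run + 1L; i <- i + 1L
  }
  i <- from - 1L
  while (i >= 1L && genome_base(genome, i) == b) {
    run <- run + 1L; i <- i - 1L
  }
  run
}

#' Build a reduced indel-channel catalog
#'
#' Classifies left-aligned, parsimonious indels into six channels:
#' 1 bp insertions and deletions split by the reference homopolymer run
#' length at the event (short <= 4, long >= 5; long-homopolymer 1 bp
#' events are ID1/ID2-like), plus >= 2 bp insertions and deletions
#' (ID5/ID8-like territory). Counts are conserved.
#'
#' @param indels data.frame with `pos`, `ref`, `alt` in VCF convention
#'   (anchor base included; e.g. ref "A", alt "AT" is a 1 bp insertion).
#' @param genome genome list (for run-length lookup).
#' @return named integer vector over the six channels.
#' @export
build_indel_catalog <- function(indels, genome) {
  counts <- stats::setNames(integer(length(INDEL_CHANNELS)), INDEL_CHANNELS)
  if (nrow(indels) == 0) return(counts)
  for (i in seq_len(nrow(indels))) {
    ref <- indels$ref[i]; alt <- indels$alt[i]
    dlen <- nchar(alt) - nchar(ref)
    if (dlen == 0) stop("not an indel: ", ref, ">", alt)
    if (abs(dlen) >= 2) {
      ch <- if (dlen > 0) "ins_2plus" else "del_2plus"
    } else {
      b <- if (dlen > 0) substr(alt, 2, 2) else substr(ref, 2, 2)
      run <- homopolymer_run(genome, indels$pos[i] + 1L, b)
      long <- run >= 5
      ch <- if (dlen > 0) {
        if (long) "ins1_homlong" else "ins1_homshort"
      } else {
        if (long) "del1_homlong" else "del1_homshort"
      }
    }
    counts[ch] <- counts[ch] + 1L
  }
  counts
}

#' Transcriptional strand asymmetry of mutation counts
#'
#' For each of the six pyrimidine substitution types, counts variants by
#' whether the pyrimidine of the mutated pair lies on the transcribed
#' (template) or untranscribed (coding) strand of the overlapping
#' transcript, and tests equality with a two-sided exact binomial test
#' (p = 0.5 on the two strand counts). Variants outside annotated
#' transcripts are excluded.
#'
#' @param variants data.frame with `ref`, `alt` and `tx_strand` (strand of
#'   the overlapping transcript, NA outside transcripts).
#' @return data.frame with one row per substitution type: transcribed and
#'   untranscribed counts, asymmetry ratio, p-value.
#' @export
strand_asymmetry <- function(variants) {
  v <- variants[!is.na(variants$tx_strand), , drop = FALSE]
  pyr_ref <- ifelse(v$ref %in% PYRIMIDINES, v$ref, complement_base(v$ref))
  pyr_alt <- ifelse(v$ref %in% PYRIMIDINES, v$alt, complement_base(v$alt))
  type <- paste0(pyr_ref, ">", pyr_alt)
  pyr_strand <- ifelse(v$ref %in% PYRIMIDINES, "+", "-")
  transcribed <- pyr_strand != v$tx_strand
  out <- lapply(SUB_TYPES, function(s) {
    n_ts <- sum(type == s & transcribed)
    n_uts <- sum(type == s & !transcribed)
    p <- if (n_ts + n_uts == 0) NA_real_ else
      binom_two_sided(n_ts, n_ts + n_uts, 0.5)
    data.frame(type = s, transcribed = n_ts, untranscribed = n_uts,
               ratio = if (n_uts > 0) n_ts / n_uts else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchically cluster exposure profiles
#'
#' Agglomerative clustering (average linkage) on cosine distances between
#' relative-contribution vectors. Rows are sorted by label before
#' clustering so the leaf order is deterministic under input reordering.
#'
#' @param exposures groups x signatures matrix of (relative) exposures.
#' @return an [stats::hclust] object (a singleton list for one group).
#' @export
cluster_exposures <- function(exposures) {
  E <- as.matrix(exposures)
  E <- E[order(rownames(E)), , drop = FALSE]
  if (nrow(E) < 2) {
    return(structure(list(labels = rownames(E), singleton = TRUE),
                     class = "singleton_dendrogram"))
  }
  n <- nrow(E)
  d <- matrix(0, n, n, dimnames = list(rownames(E), rownames(E)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - cosine_similarity(E[i, ], E[j, ])
    }
  }
  stats::hclust(stats::as.dist(d), method = "average")
}
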