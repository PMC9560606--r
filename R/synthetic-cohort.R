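# Synthetic multi-tissue cohort generator: a stated world with planted
# early/late/tumor clones, artifact classes and per-site read counts, so the
# whole calling/classification/signature/selection stack is testable with no
# external data.

# Deterministic synthetic reference contig (single chromosome).
synth_genome <- function(config) {
  set.seed(config$seed)
  seq <- paste(sample(BASES, config$genome_size, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  list(contig = config$contig, length = config$genome_size, seq = seq)
}

# Map every interior position to its forward-strand trinucleotide and index
# positions by trinucleotide for context-conditional site sampling.
genome_context_index <- function(genome) {
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tri <- paste0(chars[1:(n - 2)], chars[2:(n - 1)], chars[3:n])
  pos <- 2:(n - 1)
  list(chars = chars, tri_by_pos = tri, index = split(pos, tri))
}

genome_base <- function(genome, pos) {
  if (length(pos) == 0) return(character(0))
  substring(genome$seq, pos, pos)
}

#' Generate synthetic gene models, pLI scores and reference signatures
#'
#' Emits a small set of single-exon coding transcripts (strand, CDS
#' interval, CDS sequence and its translation), a per-gene pLI score in
#' \[0, 1\], and a channel-normalized reference-signature matrix (the
#' packaged generator spectra, standing in for an external signature
#' catalog). All outputs are synthetic stand-ins for annotation resources
#' the pipeline would normally read from files.
#'
#' @param config a [cohort_config()].
#' @param genome optional genome from an existing cohort (regenerated from
#'   the config seed when omitted).
#' @return list with elements `genes` (data.frame: gene_id, contig, start,
#'   end, strand, cds_seq, protein), `pli` (data.frame: gene_id, pli) and
#'   `ref_signatures` (96 x 4 matrix).
#' @export
generate_gene_models <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- synth_genome(config)
  set.seed(config$seed + 1L)
  n <- config$n_genes
  # Non-overlapping placement on a coarse grid.
  grid <- seq(10L, genome$length - 2000L, by = 2000L)
  starts <- sort(sample(grid, n))
  len <- 3L * sample(100:400, n, replace = TRUE)
  len <- pmin(len, 1800L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("G%03d", seq_len(n))
  cds <- substring(genome$seq, starts, starts + len - 1L)
  cds <- ifelse(strand == "-", revcomp(cds), cds)
  protein <- vapply(cds, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1), USE.NAMES = FALSE)
  genes <- data.frame(
    gene_id = gene_id, contig = genome$contig,
    start = starts, end = starts + len - 1L,
    strand = strand, cds_seq = cds, protein = protein,
    stringsAsFactors = FALSE
  )
  pli <- data.frame(gene_id = gene_id,
                    pli = round(stats::runif(n), 3),
                    stringsAsFactors = FALSE)
  list(genes = genes, pli = pli, ref_signatures = generator_spectra())
}

#' Generate disjoint BED-style blacklist tracks
#'
#' Emits the six filter tracks of the post-call cascade (common SNP sites,
#' segmental duplications, simple repeats, low mappability, off-target,
#' UTR) as mutually disjoint 0-based half-open intervals covering, in
#' total, `fraction_blacklisted` of the contig.
#'
#' @param config a [cohort_config()].
#' @return named list of data.frames with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @export
generate_blacklists <- function(config) {
  set.seed(config$seed + 2L)
  tracks <- c("common_snp", "segdup", "simple_repeat", "low_mappability",
              "off_target", "utr")
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out <- stats::setNames(rep(list(empty), length(tracks)), tracks)
  if (config$fraction_blacklisted <= 0) return(out)
  w <- 500L
  grid <- seq(0L, config$genome_size - w, by = w)
  n_per <- round(config$fraction_blacklisted / length(tracks) *
                   config$genome_size / w)
  if (n_per * length(tracks) > length(grid)) {
    stop("fraction_blacklisted too large for contig size")
  }
  starts <- sample(grid, n_per * length(tracks))
  for (i in seq_along(tracks)) {
    s <- sort(starts[seq((i - 1) * n_per + 1, i * n_per)])
    out[[tracks[i]]] <- data.frame(contig = config$contig, start = s,
                                   end = s + w, stringsAsFactors = FALSE)
  }
  out
}

# Positions (1-based) covered by any blacklist interval.
blacklist_positions <- function(blacklists) {
  unlist(lapply(blacklists, function(b) {
    if (nrow(b) == 0) return(integer(0))
    unlist(Map(seq, b$start + 1L, b$end))
  }), use.names = FALSE)
}

#' Simulate read counts for one site in one tissue
#'
#' Alternate read counts are Binomial(depth, clone VAF + error) for carrier
#' tissues and Binomial(depth, error) otherwise. Orientation-split counts
#' (F1R2/F2R1) are balanced for genuine variants; oxoG-like artifacts place
#' >= 90% of alternate reads on the artifact-prone orientation (F2R1 for
#' C>A, F1R2 for G>T).
#'
#' @param clone_vaf true clone fraction(s) in the tissue (0 for
#'   non-carriers); vectorized.
#' @param depth read depth(s), > 0.
#' @param error_rate per-base substitution error probability.
#' @param oxog logical, oxoG-like orientation bias for the artifact sites.
#' @param ref reference base(s), used only to orient the oxoG bias.
#' @return data.frame with depth, alt_count, alt_f1r2, alt_f2r1 and vaf.
#' @export
#' @examples
#' set.seed(1)
#' simulate_read_counts(0.0617, 500, 1e-3)
simulate_read_counts <- function(clone_vaf, depth, error_rate,
                                 oxog = FALSE, ref = "C") {
  if (any(depth <= 0)) stop("depth must be > 0")
  n <- max(length(clone_vaf), length(depth))
  clone_vaf <- rep_len(clone_vaf, n)
  depth <- rep_len(depth, n)
  oxog <- rep_len(oxog, n)
  ref <- rep_len(ref, n)
  p <- ifelse(clone_vaf > 0, clone_vaf + error_rate * (1 - clone_vaf),
              error_rate)
  alt <- stats::rbinom(n, depth, p)
  # balanced orientations for genuine variants; oxoG artifacts are forced
  # to keep >= 90% of alt reads on the artifact-prone orientation
  prone <- pmax(stats::rbinom(n, alt, 0.97), ceiling(0.9 * alt))
  f1r2 <- ifelse(oxog,
                 ifelse(ref == "G", prone, alt - prone),
                 stats::rbinom(n, alt, 0.5))
  data.frame(depth = depth, alt_count = alt, alt_f1r2 = f1r2,
             alt_f2r1 = alt - f1r2, vaf = alt / depth)
}

# Sample n mutation sites whose trinucleotide context follows the stage
# spectrum; avoids positions already used for this individual.
sample_context_sites <- function(n, stage, config, ctx, genes, used) {
  if (n == 0) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), channel = character(0),
                      tx_strand = character(0), stringsAsFactors = FALSE))
  }
  spectrum <- as.numeric(generator_spectra() %*%
                           config$signature_mix[stage, ])
  channels <- sbs_channels()
  tri <- channel_trinucs()
  picks <- sample.int(96, n, replace = TRUE, prob = spectrum)
  pos <- integer(n); ref <- character(n); alt <- character(n)
  info <- parse_channel(channels)
  for (i in seq_len(n)) {
    k <- picks[i]
    cand_plus <- ctx$index[[tri[k, "plus"]]]
    cand_minus <- if (tri[k, "minus"] == tri[k, "plus"]) integer(0) else
      ctx$index[[tri[k, "minus"]]]
    cand <- setdiff(c(cand_plus, cand_minus), used)
    if (length(cand) == 0) stop("context exhausted: ", channels[k])
    p <- cand[sample.int(length(cand), 1)]
    pos[i] <- p
    if (p %in% cand_plus) {
      ref[i] <- info$ref[k]; alt[i] <- info$alt[k]
    } else {
      ref[i] <- complement_base(info$ref[k])
      alt[i] <- complement_base(info$alt[k])
    }
    used <- c(used, p)
  }
  hit <- findInterval(pos, genes$start)
  tx_strand <- ifelse(hit >= 1 & pos <= genes$end[pmax(hit, 1)],
                      genes$strand[pmax(hit, 1)], NA_character_)
  data.frame(pos = pos, ref = ref, alt = alt, channel = channels[picks],
             tx_strand = tx_strand, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Generates, per individual: a set of tissues (one per configured organ,
#' plus a tumor specimen for a `tumor_fraction` of individuals), planted
#' early mutations (identical site and clone VAF in all of the individual's
#' tissues), late mutations confined to a single organ (blood counts with an
#' age-dependent Poisson mean), tumor mutations confined to the tumor
#' specimen, oxoG-like orientation-biased artifacts, artifacts planted
#' inside blacklist intervals, error-only noise sites, and per-site read
#' counts for every tissue. Deterministic given `config$seed`; each
#' individual consumes its own seeded stream, so cohorts are stable under
#' re-ordering.
#'
#' @param config a [cohort_config()].
#' @return list of class `mosaic_cohort` with elements `tissues`, `truth`,
#'   `truth_vaf` (long per-tissue true clone VAFs), `observations`, plus
#'   the generated `genome`, `genes`, `pli`, `ref_signatures`,
#'   `blacklists`, `expected_filtered` manifest and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_individuals = 2, seed = 42))
#' table(cohort$truth$stage)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genome <- synth_genome(config)
  models <- generate_gene_models(config, genome)
  blacklists <- generate_blacklists(config)
  bl_pos <- blacklist_positions(blacklists)
  ctx <- genome_context_index(genome)
  # genuine mutations are planted outside blacklist tracks; in-blacklist
  # true positives for the filter cascade are planted separately below
  if (length(bl_pos) > 0) {
    ctx$index <- lapply(ctx$index, function(p) p[!(p %in% bl_pos)])
  }

  set.seed(config$seed + 3L)
  n <- config$n_individuals
  ids <- sprintf("I%03d", seq_len(n))
  ages <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  has_tumor <- stats::runif(n) < config$tumor_fraction

  tissues_list <- list(); truth_list <- list()
  tvaf_list <- list(); obs_list <- list(); filt_list <- list()

  for (i in seq_len(n)) {
    set.seed(config$seed + 7919L + i * 131L)
    organs <- config$organs_per_individual
    tid <- paste0(ids[i], "_", organs)
    tissues <- data.frame(
      tissue_id = tid, individual = ids[i], organ = organs,
      age = ages[i], is_tumor = FALSE, stringsAsFactors = FALSE
    )
    if (has_tumor[i]) {
      tissues <- rbind(tissues, data.frame(
        tissue_id = paste0(ids[i], "_tumor"), individual = ids[i],
        organ = "brain", age = ages[i], is_tumor = TRUE,
        stringsAsFactors = FALSE))
    }
    k <- nrow(tissues)

    # --- planted mutation counts ---
    n_early <- stats::rpois(1, config$early_rate)
    late_by_organ <- vapply(organs, function(o) {
      lambda <- if (o == "blood") {
        config$blood_intercept + config$blood_slope * ages[i]
      } else {
        config$late_rate_by_organ[[o]]
      }
      stats::rpois(1, lambda)
    }, integer(1))
    n_tumor <- if (has_tumor[i]) stats::rpois(1, config$tumor_rate) else 0L

    used <- integer(0)
    plant <- function(nm, stage) {
      s <- sample_context_sites(nm, stage, config, ctx, models$genes, used)
      used <<- c(used, s$pos)
      s
    }
    early_sites <- plant(n_early, "early")
    late_sites <- plant(sum(late_by_organ), "late")
    late_sites$organ <- rep(organs, late_by_organ)
    tumor_sites <- plant(n_tumor, "tumor")

    # --- noise, oxoG artifacts, blacklist-planted artifacts ---
    avail <- setdiff(2:(genome$length - 1), c(used, bl_pos))
    noise_pos <- sample(avail, config$n_noise_sites)
    noise_ref <- genome_base(genome, noise_pos)
    noise_alt <- vapply(noise_ref, function(r) {
      sample(setdiff(BASES, r), 1)
    }, character(1), USE.NAMES = FALSE)
    n_ox <- stats::rbinom(1, config$n_noise_sites, config$oxog_rate)
    ox_idx <- which(noise_ref %in% c("C", "G"))
    ox_idx <- ox_idx[seq_len(min(n_ox, length(ox_idx)))]
    noise_alt[ox_idx] <- ifelse(noise_ref[ox_idx] == "C", "A", "T")
    is_ox <- seq_along(noise_pos) %in% ox_idx

    n_bl <- min(config$n_blacklist_artifacts, length(bl_pos))
    blart_pos <- if (n_bl > 0) sample(bl_pos, n_bl) else integer(0)
    blart_ref <- genome_base(genome, blart_pos)
    blart_alt <- vapply(blart_ref, function(r) {
      sample(setdiff(BASES, r), 1)
    }, character(1), USE.NAMES = FALSE)

    # --- truth records ---
    mk_truth <- function(sites, stage, organ, artifact) {
      if (nrow(sites) == 0) return(NULL)
      data.frame(individual = ids[i], contig = genome$contig,
                 pos = sites$pos, ref = sites$ref, alt = sites$alt,
                 channel = sites$channel, tx_strand = sites$tx_strand,
                 stage = stage, organ = organ, artifact = artifact,
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(
      mk_truth(early_sites, "early", NA_character_, FALSE),
      if (nrow(late_sites) > 0)
        mk_truth(late_sites[, c("pos", "ref", "alt", "channel",
                                "tx_strand")], "late",
                 late_sites$organ, FALSE),
      mk_truth(tumor_sites, "tumor", "tumor", FALSE)
    )

    art_truth <- rbind(
      if (length(ox_idx) > 0)
        data.frame(individual = ids[i], contig = genome$contig,
                   pos = noise_pos[ox_idx], ref = noise_ref[ox_idx],
                   alt = noise_alt[ox_idx], channel = NA_character_,
                   tx_strand = NA_character_, stage = "artifact",
                   organ = NA_character_, artifact = TRUE,
                   stringsAsFactors = FALSE),
      if (n_bl > 0)
        data.frame(individual = ids[i], contig = genome$contig,
                   pos = blart_pos, ref = blart_ref, alt = blart_alt,
                   channel = NA_character_, tx_strand = NA_character_,
                   stage = "artifact", organ = NA_character_,
                   artifact = TRUE, stringsAsFactors = FALSE)
    )

    # --- per-tissue clone VAF matrix over all sites ---
    site_df <- rbind(
      if (!is.null(truth)) truth[, c("pos", "ref", "alt")],
      if (!is.null(art_truth)) art_truth[, c("pos", "ref", "alt")],
      data.frame(pos = noise_pos[!is_ox], ref = noise_ref[!is_ox],
                 alt = noise_alt[!is_ox], stringsAsFactors = FALSE)
    )
    m <- nrow(site_df)
    vaf_mat <- matrix(0, nrow = m, ncol = k,
                      dimnames = list(NULL, tissues$tissue_id))
    oxog_mat <- matrix(FALSE, nrow = m, ncol = k,
                       dimnames = list(NULL, tissues$tissue_id))
    row_at <- 0L
    draw_vaf <- function(stage, nn) {
      p <- config$vaf_params[[stage]]
      rtruncnorm(nn, p[["mean"]], p[["sd"]])
    }
    if (n_early > 0) {
      v <- draw_vaf("early", n_early)
      vaf_mat[row_at + seq_len(n_early), ] <- v  # same clone VAF everywhere
      row_at <- row_at + n_early
    }
    if (nrow(late_sites) > 0) {
      v <- draw_vaf("late", nrow(late_sites))
      for (j in seq_len(nrow(late_sites))) {
        tcol <- paste0(ids[i], "_", late_sites$organ[j])
        vaf_mat[row_at + j, tcol] <- v[j]
      }
      row_at <- row_at + nrow(late_sites)
    }
    if (n_tumor > 0) {
      v <- draw_vaf("tumor", n_tumor)
      vaf_mat[row_at + seq_len(n_tumor), paste0(ids[i], "_tumor")] <- v
      row_at <- row_at + n_tumor
    }
    # artifact signal: one random tissue each, clone VAF 0 in truth
    art_sig <- matrix(0, nrow = m, ncol = k,
                      dimnames = list(NULL, tissues$tissue_id))
    if (length(ox_idx) > 0) {
      for (j in seq_along(ox_idx)) {
        tj <- sample.int(k, 1)
        art_sig[row_at + j, tj] <- stats::runif(1, 0.005, 0.02)
        oxog_mat[row_at + j, tj] <- TRUE
      }
      row_at <- row_at + length(ox_idx)
    }
    if (n_bl > 0) {
      for (j in seq_len(n_bl)) {
        art_sig[row_at + j, sample.int(k, 1)] <- 0.05
      }
      row_at <- row_at + n_bl
    }

    # --- read counts for every tissue x site ---
    for (t in if (m > 0) seq_len(k) else integer(0)) {
      depth <- pmax(stats::rpois(m, config$depth_mean), 1L)
      eff_vaf <- pmax(vaf_mat[, t], art_sig[, t])
      rc <- simulate_read_counts(eff_vaf, depth, config$seq_error_rate,
                                 oxog = oxog_mat[, t], ref = site_df$ref)
      obs_list[[length(obs_list) + 1L]] <- data.frame(
        tissue_id = tissues$tissue_id[t], individual = ids[i],
        contig = genome$contig, pos = site_df$pos, ref = site_df$ref,
        alt = site_df$alt, rc, stringsAsFactors = FALSE)
    }

    # --- truth clone-VAF long table (carriers only) ---
    n_truth <- if (is.null(truth)) 0L else nrow(truth)
    if (n_truth > 0) {
      carrier <- which(vaf_mat[seq_len(n_truth), , drop = FALSE] > 0,
                       arr.ind = TRUE)
      if (nrow(carrier) > 0) {
        tvaf_list[[length(tvaf_list) + 1L]] <- data.frame(
          individual = ids[i],
          tissue_id = tissues$tissue_id[carrier[, 2]],
          contig = genome$contig,
          pos = truth$pos[carrier[, 1]],
          ref = truth$ref[carrier[, 1]],
          alt = truth$alt[carrier[, 1]],
          vaf = vaf_mat[cbind(carrier[, 1], carrier[, 2])],
          stringsAsFactors = FALSE)
      }
    }

    if (n_bl > 0) {
      filt_list[[length(filt_list) + 1L]] <- data.frame(
        individual = ids[i], contig = genome$contig, pos = blart_pos,
        ref = blart_ref, alt = blart_alt, stringsAsFactors = FALSE)
    }
    tissues_list[[i]] <- tissues
    truth_list[[i]] <- rbind(truth, art_truth)
  }

  empty_truth <- data.frame(
    individual = character(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), channel = character(0),
    tx_strand = character(0), stage = character(0), organ = character(0),
    artifact = logical(0), stringsAsFactors = FALSE)
  truth <- if (length(truth_list) > 0) {
    do.call(rbind, c(truth_list, list(empty_truth)))
  } else empty_truth
  empty_tvaf <- data.frame(
    individual = character(0), tissue_id = character(0),
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), vaf = numeric(0), stringsAsFactors = FALSE)
  empty_site <- data.frame(
    individual = character(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), stringsAsFactors = FALSE)
  empty_tissues <- data.frame(
    tissue_id = character(0), individual = character(0),
    organ = character(0), age = numeric(0), is_tumor = logical(0),
    stringsAsFactors = FALSE)
  empty_obs <- data.frame(
    tissue_id = character(0), individual = character(0),
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), depth = integer(0), alt_count = integer(0),
    alt_f1r2 = integer(0), alt_f2r1 = integer(0), vaf = numeric(0),
    stringsAsFactors = FALSE)

  out <- list(
    tissues = if (length(tissues_list) > 0) do.call(rbind, tissues_list)
              else empty_tissues,
    truth = truth,
    truth_vaf = if (length(tvaf_list) > 0) do.call(rbind, tvaf_list)
                else empty_tvaf,
    observations = if (length(obs_list) > 0) do.call(rbind, obs_list)
                   else empty_obs,
    genome = genome,
    genes = models$genes,
    pli = models$pli,
    ref_signatures = models$ref_signatures,
    blacklists = blacklists,
    expected_filtered = if (length(filt_list) > 0) do.call(rbind, filt_list)
                        else empty_site,
    config = config
  )
  class(out) <- "mosaic_cohort"
  out
}

#' @export
print.mosaic_cohort <- function(x, ...) {
  cat("mosaic_cohort:", x$config$n_individuals, "individuals,",
      nrow(x$tissues), "tissues,",
      sum(!x$truth$artifact), "planted mutations (",
      paste(names(table(x$truth$stage[!x$truth$artifact])),
            table(x$truth$stage[!x$truth$artifact]), collapse = ", "),
      "),", sum(x$truth$artifact), "artifacts\n")
  invisible(x)
}
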