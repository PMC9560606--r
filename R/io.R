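# Standard-format I/O: per-tissue VCF 4.2 with AD/DP and orientation
# FORMAT fields, BED blacklists (0-based half-open), TSV tables, and the
# persisted pipeline output directory.

#' Write one tissue's observations as VCF 4.2
#'
#' FORMAT fields: GT (./.), DP, AD (ref,alt), F1R2, F2R1 (orientation-split
#' alternate read counts). Positions are 1-based per VCF convention.
#'
#' @param obs observation data.frame for one tissue.
#' @param path output file.
#' @param contig_lengths named vector of contig lengths for the header.
#' @param sample_name sample column name (defaults to the tissue id).
#' @return the path, invisibly.
#' @export
write_tissue_vcf <- function(obs, path, contig_lengths,
                             sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- if (nrow(obs) > 0) obs$tissue_id[1] else "SAMPLE"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicstage",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste0("##FORMAT=<ID=F1R2,Number=1,Type=Integer,Description=",
           "\"Alt reads on F1R2 orientation\">"),
    paste0("##FORMAT=<ID=F2R1,Number=1,Type=Integer,Description=",
           "\"Alt reads on F2R1 orientation\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  body <- if (nrow(obs) > 0) {
    ord <- order(obs$contig, obs$pos)
    o <- obs[ord, ]
    paste(o$contig, o$pos, ".", o$ref, o$alt, ".", "PASS", ".",
          "GT:DP:AD:F1R2:F2R1",
          sprintf("./.:%d:%d,%d:%d:%d", o$depth, o$depth - o$alt_count,
                  o$alt_count, o$alt_f1r2, o$alt_f2r1),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-tissue VCF back into an observation table
#'
#' Uses VariantAnnotation when available; requires the DP/AD (and
#' optionally F1R2/F2R1) FORMAT fields written by [write_tissue_vcf()].
#'
#' @param path VCF file.
#' @param tissue_id,individual identifiers to attach.
#' @return observation data.frame.
#' @export
read_tissue_vcf <- function(path, tissue_id = NA_character_,
                            individual = NA_character_) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_tissue_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  ad <- geno$AD[, 1]
  alt_count <- vapply(ad, function(x) as.integer(x[2]), integer(1))
  depth <- as.integer(geno$DP[, 1])
  f1r2 <- if ("F1R2" %in% names(geno)) as.integer(geno$F1R2[, 1]) else
    NA_integer_
  f2r1 <- if ("F2R1" %in% names(geno)) as.integer(geno$F2R1[, 1]) else
    NA_integer_
  data.frame(
    tissue_id = tissue_id, individual = individual,
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
    depth = depth, alt_count = alt_count,
    alt_f1r2 = f1r2, alt_f2r1 = f2r1,
    vaf = alt_count / depth, stringsAsFactors = FALSE)
}

#' Write a blacklist track as BED
#'
#' @param track data.frame with contig/start/end (0-based half-open).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed <- function(track, path) {
  if (nrow(track) == 0) {
    file.create(path)
  } else {
    utils::write.table(track, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file as a blacklist track
#'
#' Uses rtracklayer's BED import when available; coordinates are returned
#' 0-based half-open to match [generate_blacklists()]. A malformed line
#' raises an error naming the line number.
#'
#' @param path BED file.
#' @return data.frame with contig, start, end.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("malformed BED file ", path,
                                            ": ", conditionMessage(e)))
    return(data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad) > 0) stop("malformed BED line ", bad[1], " in ", path)
  data.frame(contig = vapply(parts, `[`, character(1), 1),
             start = as.integer(vapply(parts, `[`, character(1), 2)),
             end = as.integer(vapply(parts, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist every pipeline stage's outputs
#'
#' Writes per-tissue VCFs, BED blacklists, the truth/classified/summary
#' TSVs and a JSON run log (seed, config hash, counts in/out per filter).
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- result$cohort
  clen <- stats::setNames(co$genome$length, co$genome$contig)
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (tid in unique(co$observations$tissue_id)) {
    write_tissue_vcf(co$observations[co$observations$tissue_id == tid, ],
                     file.path(vcf_dir, paste0(tid, ".vcf")), clen)
  }
  bed_dir <- file.path(out_dir, "blacklists")
  dir.create(bed_dir, showWarnings = FALSE)
  for (track in names(co$blacklists)) {
    write_bed(co$blacklists[[track]],
              file.path(bed_dir, paste0(track, ".bed")))
  }
  write_tsv(co$tissues, file.path(out_dir, "tissues.tsv"))
  write_tsv(co$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(co$genes[, c("gene_id", "contig", "start", "end", "strand")],
            file.path(out_dir, "gene_models.tsv"))
  write_tsv(co$pli, file.path(out_dir, "pli.tsv"))
  write_tsv(data.frame(channel = rownames(co$ref_signatures),
                       co$ref_signatures),
            file.path(out_dir, "ref_signatures.tsv"))
  write_tsv(result$classified, file.path(out_dir, "classified_variants.tsv"))
  write_tsv(result$per_tissue, file.path(out_dir, "classified_per_tissue.tsv"))
  write_tsv(result$verdicts, file.path(out_dir, "filter_verdicts.tsv"))
  write_tsv(result$summaries, file.path(out_dir, "group_summaries.tsv"))
  write_tsv(result$validation$per_stage, file.path(out_dir,
                                                   "validation.tsv"))
  log <- list(
    package_version = as.character(utils::packageVersion("mosaicstage")),
    seed = co$config$seed,
    config_hash = config_hash(co$config),
    n_candidates = nrow(result$candidates),
    n_considered = nrow(result$verdicts),
    n_filtered = sum(!result$verdicts$keep),
    n_classified = nrow(result$classified),
    filter_attrition = if (nrow(result$verdicts) > 0) {
      tracks <- setdiff(names(result$verdicts),
                        c("individual", "contig", "pos", "ref", "alt",
                          "keep"))
      as.list(vapply(result$verdicts[tracks],
                     function(x) sum(!x), numeric(1)))
    } else list()
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

# Stable hash of the configuration for the run log.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # simple polynomial rolling hash over the serialized text; avoids extra
  # dependencies
  h <- 0
  for (ch in utf8ToInt(s)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
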