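# 96-channel trinucleotide context machinery shared by the generator, the
# catalog builder and the selection model.

PYRIMIDINES <- c("C", "T")
BASES <- c("A", "C", "G", "T")
SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Complement / reverse-complement of short base strings
#'
#' Plain-character helpers used throughout; genomic-scale sequence work goes
#' through Biostrings.
#' @param x character vector of A/C/G/T strings.
#' @return character vector of the same length.
#' @keywords internal
complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname complement_base
#' @keywords internal
revcomp <- function(x) {
  vapply(strsplit(complement_base(x), ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' The 96 single-base-substitution channels
#'
#' Channel names follow the conventional `U[R>A]D` layout (upstream base,
#' pyrimidine reference > alternate, downstream base), ordered by
#' substitution type (C>A, C>G, C>T, T>A, T>C, T>G) and then by flanking
#' bases, matching the layout used by signature tools such as
#' MutationalPatterns.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  out <- character(0)
  for (sub in SUB_TYPES) {
    ref <- substr(sub, 1, 1)
    alt <- substr(sub, 3, 3)
    for (up in BASES) {
      for (down in BASES) {
        out <- c(out, paste0(up, "[", ref, ">", alt, "]", down))
      }
    }
  }
  out
}

#' Collapse a substitution with flanks into its pyrimidine-context channel
#'
#' Purine-reference substitutions are reverse-complemented so that the
#' reference base of every channel is a pyrimidine.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param up,down 5' and 3' flanking bases on the reference strand.
#' @return character vector of channel names as in [sbs_channels()].
#' @export
classify_context <- function(ref, alt, up, down) {
  stopifnot(length(ref) == length(alt), length(up) == length(ref),
            length(down) == length(ref))
  flip <- !(ref %in% PYRIMIDINES)
  r <- ifelse(flip, complement_base(ref), ref)
  a <- ifelse(flip, complement_base(alt), alt)
  u <- ifelse(flip, complement_base(down), up)
  d <- ifelse(flip, complement_base(up), down)
  paste0(u, "[", r, ">", a, "]", d)
}

# Parse "A[C>T]G" into its components.
parse_channel <- function(channel) {
  data.frame(
    up = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    down = substr(channel, 7, 7),
    stringsAsFactors = FALSE
  )
}

# Forward-strand trinucleotides compatible with each channel: the pyrimidine
# representation and its reverse complement. Returns a 96 x 2 character
# matrix (columns: pyr-on-plus trinuc, pyr-on-minus trinuc).
channel_trinucs <- function() {
  ch <- parse_channel(sbs_channels())
  fwd <- paste0(ch$up, ch$ref, ch$down)
  rev <- revcomp(fwd)
  cbind(plus = fwd, minus = rev)
}
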