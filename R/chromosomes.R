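## Human contig naming, ordering and lengths shared across the package.

.HUMAN_CHROMS <- paste0("chr", c(1:22, "X", "Y"))

#' Normalize a human chromosome name
#'
#' Accepts both `"chr"`-prefixed and bare names (`"17"`, `"chr17"`, `"X"`)
#' and returns the canonical `"chr"`-prefixed form. Names that are not one of
#' chr1-chr22, chrX, chrY are rejected (or return `NA` with `strict = FALSE`).
#'
#' @param x character vector of chromosome names.
#' @param strict error on unrecognized contigs (default) instead of `NA`.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_chromosome(c("1", "chrX", "22"))
normalize_chromosome <- function(x, strict = TRUE) {
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  out <- ifelse(bare %in% c(1:22, "X", "Y"), paste0("chr", bare), NA_character_)
  if (strict && anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognized human chromosome name(s): ", paste(bad, collapse = ", "),
         " (expected chr1-chr22, chrX, chrY, with or without 'chr')",
         call. = FALSE)
  }
  out
}

#' @return integer rank: chr1 < ... < chr22 < chrX < chrY.
#' @noRd
chromosome_rank <- function(x) {
  match(normalize_chromosome(x), .HUMAN_CHROMS)
}

#' Is this an autosome (chr1-chr22)?
#' @noRd
is_autosome <- function(x) {
  chromosome_rank(x) <= 22L
}

## Canonical contig lengths for the two supported builds (UCSC primary
## assemblies). Bundled as constants so cumulative genome coordinates need no
## network access.
.CONTIG_LENGTHS <- list(
  hg19 = c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566),
  hg38 = c(
    chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415)
)

#' Contig lengths for a supported genome build
#'
#' @param genome `"hg19"` or `"hg38"`.
#' @return named numeric vector of lengths for chr1-chr22, chrX, chrY.
#' @export
contig_lengths <- function(genome = c("hg38", "hg19")) {
  genome <- match.arg(genome)
  .CONTIG_LENGTHS[[genome]]
}

#' Cumulative start offset of each contig in a linearized genome
#' @noRd
contig_offsets <- function(genome) {
  len <- contig_lengths(genome)
  stats::setNames(cumsum(c(0, unname(len[-length(len)]))), names(len))
}
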