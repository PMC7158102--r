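## Minimal BED reader with per-line diagnostics.
##
## The panel inputs are plain 3/4-column BED (0-based half-open). We read them
## directly so malformed lines can be rejected with the file name and line
## number the error contract requires; importers for richer formats go through
## the usual Bioconductor readers.

read_bed <- function(path, label_default = NA_character_) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t| +")
  bad_line <- function(i, why) {
    stop(sprintf("malformed BED line %d in %s: %s", lineno[i], path, why),
         call. = FALSE)
  }
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  label <- rep(label_default, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) bad_line(i, "fewer than 3 columns")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) bad_line(i, "non-integer start/end")
    if (s < 0L) bad_line(i, "negative start")
    if (s >= e) bad_line(i, sprintf("start (%d) must be < end (%d)", s, e))
    ch <- tryCatch(normalize_chromosome(f[1]), error = function(err) NULL)
    if (is.null(ch)) bad_line(i, paste0("unrecognized chromosome '", f[1], "'"))
    chrom[i] <- ch; start[i] <- s; end[i] <- e
    if (length(f) >= 4L && nzchar(f[4])) label[i] <- f[4]
  }
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

## 0-based half-open interval overlap (>= 1 bp).
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

## TRUE for each row of `df` (chrom/start/end) overlapping any row of `bl`.
overlaps_any <- function(df, bl) {
  if (nrow(bl) == 0L || nrow(df) == 0L) return(rep(FALSE, nrow(df)))
  vapply(seq_len(nrow(df)), function(i) {
    same <- bl$chrom == df$chrom[i]
    any(same & intervals_overlap(df$start[i], df$end[i],
                                 bl$start[same], bl$end[same]))
  }, logical(1))
}

## Sort interval data frame by (chromosome order, start, end, label).
sort_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  ord <- order(chromosome_rank(df$chrom), df$start, df$end,
               if (!is.null(df$label)) df$label else seq_len(nrow(df)))
  df[ord, , drop = FALSE]
}
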