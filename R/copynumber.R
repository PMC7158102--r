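## Copy-number ratio engine.
##
## For each captured interval the tumor/normal copy-number ratio is
##
##     R = (T / T_nf) / (N / N_nf)
##
## where T and N are the interval's read depths in tumor and normal and
## T_nf, N_nf are per-sample normalization factors: the mean depth over the
## intervals on the normalization chromosome set. The default set is the
## autosomes (chr1-chr22); restricting it to user-chosen chromosomes guards
## the factors against whole-chromosome aberrations (a uniformly doubled
## tumor would otherwise normalize to R = 1 everywhere). Alternatively the
## ratios precomputed by the upstream depth tool can be used verbatim.

#' Normalization specification for copy-number ratios
#'
#' @param mode one of `"autosome_default"` (mean depth over chr1-chr22, the
#'   default when the depth tool provided no ratios), `"user_chromosomes"`
#'   (mean over exactly the chromosomes given), or `"provider_ratio"` (use the
#'   precomputed ratio column from the depth tables verbatim).
#' @param chromosomes chromosome names, required iff
#'   `mode = "user_chromosomes"`.
#' @return a `norm_spec` object.
#' @export
#' @examples
#' norm_spec()
#' norm_spec("user_chromosomes", c("chr2", "chr11"))
norm_spec <- function(mode = c("autosome_default", "user_chromosomes",
                               "provider_ratio"),
                      chromosomes = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_chromosomes") {
    if (is.null(chromosomes) || length(chromosomes) == 0) {
      stop("user_chromosomes mode requires a non-empty chromosome set",
           call. = FALSE)
    }
    chromosomes <- unique(normalize_chromosome(chromosomes))
  } else if (!is.null(chromosomes)) {
    stop("chromosomes may only be given with mode = 'user_chromosomes'",
         call. = FALSE)
  }
  structure(list(mode = mode, chromosomes = chromosomes), class = "norm_spec")
}

spec_selects <- function(spec, chrom) {
  switch(spec$mode,
         autosome_default = is_autosome(chrom),
         user_chromosomes = normalize_chromosome(chrom) %in% spec$chromosomes,
         stop("no chromosome selection under mode ", spec$mode, call. = FALSE))
}

describe_spec <- function(spec) {
  switch(spec$mode,
         autosome_default = "autosomes chr1-chr22",
         user_chromosomes = paste(spec$chromosomes, collapse = ","),
         provider_ratio = "provider ratios")
}

#' Normalization factor: mean depth over the selected chromosomes
#'
#' @param depths data frame with columns `chrom` and `depth` for one sample
#'   role (blacklisted intervals should already be excluded).
#' @param spec a [norm_spec()] with a chromosome selection
#'   (`autosome_default` or `user_chromosomes`).
#' @return the arithmetic mean depth over intervals on selected chromosomes.
#' @export
normalization_factor <- function(depths, spec = norm_spec()) {
  stopifnot(is.data.frame(depths), all(c("chrom", "depth") %in% names(depths)))
  if (!inherits(spec, "norm_spec")) stop("spec must be a norm_spec", call. = FALSE)
  sel <- spec_selects(spec, depths$chrom)
  if (!any(sel)) {
    stop("no intervals on the normalization chromosomes (",
         describe_spec(spec), ")", call. = FALSE)
  }
  nf <- mean(depths$depth[sel])
  if (nf == 0) {
    stop("degenerate sample: mean depth over the normalization set is zero",
         call. = FALSE)
  }
  nf
}

#' Compute the tumor/normal copy-number ratio track for a sample
#'
#' Applies `R = (T/T_nf)/(N/N_nf)` per non-blacklisted panel interval with
#' both depths present, or copies the provider's precomputed ratios when
#' `spec` has mode `"provider_ratio"`. Intervals with zero normal depth are
#' excluded and reported in the result's `dropped` element. Blacklisted
#' intervals contribute neither entries nor normalization factors.
#'
#' @param db a `panel_db` handle.
#' @param sample_id a registered sample with imported depths.
#' @param spec a [norm_spec()].
#' @return a `ratio_track` object: list with `sample_id`, `spec`,
#'   `tumor_norm_factor`, `normal_norm_factor` (both `NA` for provider
#'   ratios), `genome`, `entries` (data frame with target coordinates,
#'   `tumor_depth`, `normal_depth`, `ratio`) and `dropped`.
#' @export
compute_ratio_track <- function(db, sample_id, spec = norm_spec()) {
  if (!inherits(spec, "norm_spec")) stop("spec must be a norm_spec", call. = FALSE)
  d <- sample_depths(db, sample_id)
  if (nrow(d) == 0) stop("sample ", sample_id, " has no imported depths",
                         call. = FALSE)
  tum <- d[d$role == "tumor", ]
  nor <- d[d$role == "normal", ]
  if (nrow(tum) == 0 || nrow(nor) == 0) {
    stop("sample ", sample_id, " needs both tumor and normal depths",
         call. = FALSE)
  }
  keep <- intersect(tum$target_id, nor$target_id)
  bl <- panel_blacklist(db)
  tum <- tum[match(keep, tum$target_id), ]
  nor <- nor[match(keep, nor$target_id), ]
  blacklisted <- overlaps_any(tum, bl)
  tum <- tum[!blacklisted, ]; nor <- nor[!blacklisted, ]
  if (nrow(tum) == 0) stop("all intervals with depths are blacklisted", call. = FALSE)

  entries <- data.frame(target_id = tum$target_id, chrom = tum$chrom,
                        start = tum$start, end = tum$end, label = tum$label,
                        tumor_depth = tum$depth, normal_depth = nor$depth,
                        stringsAsFactors = FALSE)
  if (spec$mode == "provider_ratio") {
    if (anyNA(tum$precomputed_ratio)) {
      stop("provider_ratio mode requires a precomputed ratio for every ",
           "interval; depth tables for ", sample_id, " lack one", call. = FALSE)
    }
    entries$ratio <- tum$precomputed_ratio
    t_nf <- NA_real_; n_nf <- NA_real_
    dropped <- entries[0, ]
  } else {
    if (all(nor$depth == 0)) stop("all normal depths are zero for ", sample_id,
                                  call. = FALSE)
    t_nf <- normalization_factor(
      data.frame(chrom = tum$chrom, depth = tum$depth), spec)
    n_nf <- normalization_factor(
      data.frame(chrom = nor$chrom, depth = nor$depth), spec)
    zero_n <- entries$normal_depth == 0
    dropped <- entries[zero_n, ]
    entries <- entries[!zero_n, ]
    if (nrow(dropped)) {
      message(nrow(dropped), " interval(s) with zero normal depth excluded ",
              "from the ratio track")
    }
    entries$ratio <- (entries$tumor_depth / t_nf) / (entries$normal_depth / n_nf)
  }
  rownames(entries) <- NULL
  structure(list(sample_id = sample_id, spec = spec,
                 tumor_norm_factor = t_nf, normal_norm_factor = n_nf,
                 genome = panel_info(db)$reference_genome,
                 entries = entries, dropped = dropped),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("copy-number ratio track for sample '%s' (%s)\n",
              x$sample_id, x$genome))
  cat(sprintf("  normalization: %s", describe_spec(x$spec)))
  if (x$spec$mode != "provider_ratio") {
    cat(sprintf(" (T_nf = %.4g, N_nf = %.4g)",
                x$tumor_norm_factor, x$normal_norm_factor))
  }
  cat(sprintf("\n  %d intervals; ratio range [%.3g, %.3g]; %d dropped (N = 0)\n",
              nrow(x$entries), min(x$entries$ratio), max(x$entries$ratio),
              nrow(x$dropped)))
  invisible(x)
}

check_thresholds <- function(loss_max, gain_min) {
  if (!is.numeric(loss_max) || !is.numeric(gain_min) || loss_max >= gain_min) {
    stop("thresholds must satisfy loss_max < gain_min (got ", loss_max,
         ", ", gain_min, ")", call. = FALSE)
  }
}

cn_state <- function(ratio, loss_max, gain_min) {
  ifelse(ratio <= loss_max, "deleted",
         ifelse(ratio >= gain_min, "gained", "neutral"))
}

#' Automatic per-interval copy-number calls
#'
#' Classifies every track entry from its ratio alone: `deleted` when
#' `R <= loss_max`, `gained` when `R >= gain_min`, else `neutral` (boundaries
#' inclusive toward the aberrant state). The default thresholds 0.75 / 1.25
#' are the midpoints between clonal one-, two- and three-copy ratios.
#'
#' @param track a `ratio_track`.
#' @param loss_max deletion threshold on the linear ratio scale.
#' @param gain_min gain threshold on the linear ratio scale.
#' @return data frame: track entry coordinates plus `ratio` and `state`, in
#'   track order.
#' @export
auto_cn_calls <- function(track, loss_max = 0.75, gain_min = 1.25) {
  stopifnot(inherits(track, "ratio_track"))
  check_thresholds(loss_max, gain_min)
  e <- track$entries
  data.frame(chrom = e$chrom, start = e$start, end = e$end, label = e$label,
             ratio = e$ratio,
             state = cn_state(e$ratio, loss_max, gain_min),
             stringsAsFactors = FALSE)
}

#' Automatic per-gene-group copy-number calls
#'
#' Summarizes each gene group's member-interval ratios (median by default;
#' mean optionally) and applies the same thresholds as [auto_cn_calls()].
#' Groups with no scored member intervals are reported `uncallable` with
#' `n_intervals = 0`.
#'
#' @param track a `ratio_track`.
#' @param groups group membership as returned by [panel_groups()].
#' @param loss_max,gain_min thresholds as in [auto_cn_calls()].
#' @param summary `"median"` (default) or `"mean"`.
#' @return data frame with `group_name`, `summary_ratio`, `state`,
#'   `n_intervals`.
#' @export
auto_cn_group_calls <- function(track, groups, loss_max = 0.75,
                                gain_min = 1.25,
                                summary = c("median", "mean")) {
  stopifnot(inherits(track, "ratio_track"))
  summary <- match.arg(summary)
  check_thresholds(loss_max, gain_min)
  fun <- if (summary == "median") stats::median else mean
  e <- track$entries
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  ek <- key(e)
  names <- unique(groups$group_name)
  out <- lapply(names, function(g) {
    mem <- groups[groups$group_name == g & !is.na(groups$chrom), , drop = FALSE]
    ratios <- e$ratio[ek %in% key(mem)]
    if (length(ratios) == 0) {
      data.frame(group_name = g, summary_ratio = NA_real_,
                 state = "uncallable", n_intervals = 0L,
                 stringsAsFactors = FALSE)
    } else {
      s <- fun(ratios)
      data.frame(group_name = g, summary_ratio = s,
                 state = cn_state(s, loss_max, gain_min),
                 n_intervals = length(ratios), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' B-allele-frequency points for the SNP / LOH view
#'
#' Computes normal and tumor variant-allele fractions from allelic depths.
#' A SNP counts as heterozygous in the normal when its normal VAF falls inside
#' `het_band` (closed interval); downstream SNP panels show only those points,
#' where a tumor VAF diverging from ~0.5 indicates allelic imbalance or loss
#' of heterozygosity. Sites with zero total depth in either sample are
#' excluded (their VAF is undefined).
#'
#' @param records data frame of allelic records as from [snp_records()]
#'   (columns `chrom`, `pos`, `normal_ref`, `normal_alt`, `tumor_ref`,
#'   `tumor_alt`).
#' @param het_band numeric `c(low, high)` within `[0, 1]`, default
#'   `c(0.4, 0.6)`.
#' @return data frame with `chrom`, `pos`, `normal_vaf`, `tumor_vaf`,
#'   `heterozygous_in_normal`.
#' @export
compute_baf <- function(records, het_band = c(0.4, 0.6)) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "normal_ref", "normal_alt",
                  "tumor_ref", "tumor_alt") %in% names(records)))
  if (length(het_band) != 2 || het_band[1] >= het_band[2] ||
      het_band[1] < 0 || het_band[2] > 1) {
    stop("het_band must be c(low, high) with 0 <= low < high <= 1", call. = FALSE)
  }
  ntot <- records$normal_ref + records$normal_alt
  ttot <- records$tumor_ref + records$tumor_alt
  keep <- ntot > 0 & ttot > 0
  r <- records[keep, , drop = FALSE]
  nv <- r$normal_alt / (r$normal_ref + r$normal_alt)
  tv <- r$tumor_alt / (r$tumor_ref + r$tumor_alt)
  data.frame(chrom = r$chrom, pos = r$pos, normal_vaf = nv, tumor_vaf = tv,
             heterozygous_in_normal = nv >= het_band[1] & nv <= het_band[2],
             stringsAsFactors = FALSE, row.names = NULL)
}
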