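## Deterministic plot specifications for the five views, plus rasterization.
##
## All testing happens on the spec (point positions, color classes, arcs);
## the rasterizer only consumes a spec and draws it, so rendered pixels never
## enter a test.

.CN_COLORS <- c(gained = "red", neutral = "black", deleted = "blue")

new_plot_spec <- function(view, points, arcs = NULL, axes = list()) {
  if (is.null(arcs)) {
    arcs <- data.frame(chrom_a = character(), pos_a = numeric(),
                       chrom_b = character(), pos_b = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(view = view, points = points, arcs = arcs, axes = axes),
            class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("plot spec '%s': %d points, %d arcs\n",
              x$view, nrow(x$points), nrow(x$arcs)))
  invisible(x)
}

genome_x <- function(chrom, pos, genome) {
  contig_offsets(genome)[chrom] + pos
}

#' Whole-genome copy-number view specification
#'
#' One dot per track interval at its cumulative genomic coordinate (contig
#' offsets from the panel's genome build), colored by its automatic call
#' state: gained intervals red, neutral black, deleted blue.
#'
#' @param track a `ratio_track`.
#' @param calls calls from [auto_cn_calls()] on the same track.
#' @return a `plot_spec` with chromosome boundaries in `axes$boundaries`.
#' @export
whole_genome_spec <- function(track, calls) {
  stopifnot(inherits(track, "ratio_track"))
  e <- track$entries
  if (nrow(e) == 0) stop("empty ratio track", call. = FALSE)
  if (nrow(calls) != nrow(e) ||
      !all(calls$chrom == e$chrom & calls$start == e$start)) {
    stop("calls are not aligned to the track entries", call. = FALSE)
  }
  genome <- track$genome
  mid <- (e$start + e$end) / 2
  points <- data.frame(x = unname(genome_x(e$chrom, mid, genome)),
                       y = e$ratio, color_class = calls$state,
                       label = e$label, chrom = e$chrom,
                       stringsAsFactors = FALSE)
  new_plot_spec("whole_genome", points,
                axes = list(xlab = "genomic position", ylab = "tumor/normal ratio",
                            genome = genome,
                            boundaries = contig_offsets(genome)))
}

#' Single-chromosome copy-number view specification
#'
#' Intervals of one chromosome, positioned genomically or — with
#' `continuous = TRUE` — equidistantly (x = 0, 1, 2, ... in genomic order) so
#' per-gene patterns stand out. Dots are colored by the gene region
#' (group) they belong to; intervals in no group fall back to their label.
#'
#' @param track a `ratio_track`.
#' @param chromosome chromosome to show.
#' @param continuous equidistant x positions instead of genomic ones.
#' @param groups optional group membership from [panel_groups()] used for
#'   coloring.
#' @return a `plot_spec`.
#' @export
chromosome_spec <- function(track, chromosome, continuous = FALSE,
                            groups = NULL) {
  stopifnot(inherits(track, "ratio_track"))
  ch <- normalize_chromosome(chromosome)
  e <- track$entries[track$entries$chrom == ch, , drop = FALSE]
  if (nrow(e) == 0) stop("no track intervals on ", ch, call. = FALSE)
  e <- e[order(e$start, e$end), , drop = FALSE]
  color <- e$label
  if (!is.null(groups)) {
    key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
    g <- groups[!is.na(groups$chrom), , drop = FALSE]
    hit <- match(key(e), key(g))
    color <- ifelse(is.na(hit), e$label, g$group_name[hit])
  }
  x <- if (continuous) seq_len(nrow(e)) - 1 else (e$start + e$end) / 2
  points <- data.frame(x = x, y = e$ratio, color_class = color,
                       label = e$label, chrom = e$chrom,
                       stringsAsFactors = FALSE)
  new_plot_spec(if (continuous) "chromosome_continuous" else "chromosome",
                points,
                axes = list(xlab = if (continuous) "interval index"
                                   else "position",
                            ylab = "tumor/normal ratio", chromosome = ch))
}

#' SNP / B-allele-frequency panel specification
#'
#' One point per SNP heterozygous in the normal within the selected region,
#' carrying the paired normal and tumor VAF series (`y` is the tumor VAF,
#' `y_normal` the normal VAF). Tumor VAFs diverging from the normal band
#' expose loss of heterozygosity.
#'
#' @param baf data frame from [compute_baf()].
#' @param region a chromosome name, or `list(chromosome=, start=, end=)`
#'   with 1-based positions.
#' @return a `plot_spec` (possibly with zero points).
#' @export
snp_panel_spec <- function(baf, region) {
  if (is.character(region)) region <- list(chromosome = region)
  ch <- normalize_chromosome(region$chromosome)
  keep <- baf$chrom == ch & baf$heterozygous_in_normal
  if (!is.null(region$start)) keep <- keep & baf$pos >= region$start
  if (!is.null(region$end)) keep <- keep & baf$pos <= region$end
  b <- baf[keep, , drop = FALSE]
  b <- b[order(b$pos), , drop = FALSE]
  points <- data.frame(x = b$pos, y = b$tumor_vaf, y_normal = b$normal_vaf,
                       color_class = rep("het_snp", nrow(b)),
                       label = sprintf("%s:%d", b$chrom, b$pos),
                       chrom = b$chrom, stringsAsFactors = FALSE)
  new_plot_spec("snp_panel", points,
                axes = list(xlab = "position", ylab = "VAF",
                            chromosome = ch, band = c(0, 1)))
}

## One arc per structural event. Both mates of a breakend pair collapse to a
## single arc, keyed by their MATEID pairing when present, else by the
## unordered endpoint pair.
sv_arcs <- function(svs, show_interchromosomal) {
  if (nrow(svs) == 0) return(NULL)
  a_chrom <- svs$chrom
  a_pos <- svs$pos
  b_chrom <- ifelse(!is.na(svs$partner_chrom), svs$partner_chrom, svs$chrom)
  b_pos <- ifelse(!is.na(svs$partner_pos), svs$partner_pos,
                  ifelse(!is.na(svs$end), svs$end, svs$pos))
  inter <- b_chrom != a_chrom
  keep <- !inter | show_interchromosomal
  key <- vapply(seq_len(nrow(svs)), function(i) {
    if (!is.na(svs$mate_id[i]) && nzchar(svs$mate_id[i]) &&
        !is.na(svs$record_id[i])) {
      paste(sort(c(svs$record_id[i], svs$mate_id[i])), collapse = "~")
    } else {
      ends <- sort(c(sprintf("%s:%d", a_chrom[i], a_pos[i]),
                     sprintf("%s:%d", b_chrom[i], b_pos[i])))
      paste(ends, collapse = "~")
    }
  }, character(1))
  keep <- keep & !duplicated(key)
  if (!any(keep)) return(NULL)
  data.frame(chrom_a = a_chrom[keep], pos_a = a_pos[keep],
             chrom_b = b_chrom[keep], pos_b = b_pos[keep],
             stringsAsFactors = FALSE)
}

#' Circos-style genome view specification
#'
#' Combines up to three feature rings: copy-number dots, mutation ticks, and
#' structural-variant arcs. Intra-chromosomal arcs are always included when
#' SVs are shown; inter-chromosomal arcs (translocations) only with
#' `show_interchromosomal = TRUE`. Breakend mate pairs are deduplicated to one
#' arc.
#'
#' @param track a `ratio_track` (needed when `show_cn`).
#' @param calls calls from [auto_cn_calls()] aligned to `track`.
#' @param variants mutation rows as from [mutation_table()] (needed when
#'   `show_mutations`).
#' @param svs SV rows as from [sv_table()] (needed when `show_svs`).
#' @param show_cn,show_mutations,show_svs which rings to populate; at least
#'   one must be `TRUE`.
#' @param show_interchromosomal include inter-chromosomal arcs.
#' @return a `plot_spec` whose points carry a `ring` column.
#' @export
circos_spec <- function(track = NULL, calls = NULL, variants = NULL,
                        svs = NULL, show_cn = TRUE, show_mutations = TRUE,
                        show_svs = TRUE, show_interchromosomal = FALSE) {
  if (!show_cn && !show_mutations && !show_svs) {
    stop("at least one of show_cn, show_mutations, show_svs must be TRUE",
         call. = FALSE)
  }
  genome <- if (!is.null(track)) track$genome else "hg38"
  pts <- list()
  if (show_cn) {
    if (is.null(track) || is.null(calls)) {
      stop("show_cn requires a track and calls", call. = FALSE)
    }
    e <- track$entries
    pts$cn <- data.frame(
      x = unname(genome_x(e$chrom, (e$start + e$end) / 2, genome)),
      y = e$ratio, color_class = calls$state, label = e$label,
      chrom = e$chrom, ring = "cn", stringsAsFactors = FALSE)
  }
  if (show_mutations) {
    if (is.null(variants)) stop("show_mutations requires variant rows",
                                call. = FALSE)
    if (nrow(variants)) {
      pts$mut <- data.frame(
        x = unname(genome_x(variants$chrom, variants$pos, genome)),
        y = 1, color_class = "mutation",
        label = ifelse(nzchar(variants$gene_symbol), variants$gene_symbol,
                       sprintf("%s:%d", variants$chrom, variants$pos)),
        chrom = variants$chrom, ring = "mutation", stringsAsFactors = FALSE)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else {
    data.frame(x = numeric(), y = numeric(), color_class = character(),
               label = character(), chrom = character(), ring = character(),
               stringsAsFactors = FALSE)
  }
  rownames(points) <- NULL
  arcs <- NULL
  if (show_svs) {
    if (is.null(svs)) stop("show_svs requires SV rows", call. = FALSE)
    arcs <- sv_arcs(svs, show_interchromosomal)
  }
  new_plot_spec("circos", points, arcs,
                axes = list(genome = genome,
                            show_interchromosomal = show_interchromosomal))
}

## Deterministic color for a gene-group class: hash of the name into a fixed
## palette, so colors never depend on plotting order.
group_color <- function(name) {
  pal <- grDevices::palette.colors(8, palette = "Okabe-Ito")
  idx <- vapply(name, function(s) {
    sum(utf8ToInt(s)) %% length(pal) + 1L
  }, integer(1))
  unname(pal[idx])
}

point_colors <- function(points) {
  ifelse(points$color_class %in% names(.CN_COLORS),
         .CN_COLORS[points$color_class],
         ifelse(points$color_class == "mutation", "darkorange",
                ifelse(points$color_class == "het_snp", "purple",
                       group_color(points$color_class))))
}

#' Rasterize a plot specification to an image file
#'
#' Drawing consumes only the spec; nothing is recomputed.
#'
#' @param spec a `plot_spec`.
#' @param out output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @return invisibly, `out`.
#' @export
rasterize <- function(spec, out, format = "png") {
  stopifnot(inherits(spec, "plot_spec"))
  if (!is.character(format) || length(format) != 1 ||
      !format %in% c("png", "svg", "pdf")) {
    stop("unsupported format '", format,
         "'; supported formats are png, svg, pdf", call. = FALSE)
  }
  opened <- tryCatch({
    switch(format,
           png = grDevices::png(out, width = 1000, height = 500),
           svg = grDevices::svg(out, width = 10, height = 5),
           pdf = grDevices::pdf(out, width = 10, height = 5))
    TRUE
  }, error = function(e) {
    stop("cannot open output device for ", out, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  if (spec$view == "circos") {
    draw_circos(spec)
  } else if (spec$view == "snp_panel") {
    draw_snp_panel(spec)
  } else {
    draw_scatter(spec)
  }
  invisible(out)
}

draw_scatter <- function(spec) {
  p <- spec$points
  if (nrow(p) == 0) {
    graphics::plot.new(); graphics::title(main = spec$view); return(invisible())
  }
  graphics::plot(p$x, p$y, col = point_colors(p), pch = 16, cex = 0.6,
                 xlab = spec$axes$xlab %||% "x",
                 ylab = spec$axes$ylab %||% "y", main = spec$view)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  if (!is.null(spec$axes$boundaries)) {
    graphics::abline(v = unname(spec$axes$boundaries), col = "grey85")
  }
}

draw_snp_panel <- function(spec) {
  p <- spec$points
  graphics::plot(NA, xlim = range(c(p$x, 0, 1)), ylim = c(0, 1),
                 xlab = spec$axes$xlab %||% "position", ylab = "VAF",
                 main = sprintf("SNPs %s", spec$axes$chromosome %||% ""))
  if (nrow(p)) {
    graphics::points(p$x, p$y_normal, col = "grey40", pch = 1, cex = 0.7)
    graphics::points(p$x, p$y, col = "purple", pch = 16, cex = 0.7)
  }
  graphics::abline(h = 0.5, lty = 3, col = "grey60")
}

draw_circos <- function(spec) {
  genome <- spec$axes$genome %||% "hg38"
  len <- contig_lengths(genome)
  total <- sum(len)
  off <- contig_offsets(genome)
  ang <- function(chrom, pos) 2 * pi * (off[chrom] + pos) / total
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = "circos")
  th <- seq(0, 2 * pi, length.out = 360)
  graphics::lines(cos(th), sin(th), col = "grey70")
  for (ch in names(len)) {
    a <- ang(ch, 0)
    graphics::segments(0.95 * cos(a), 0.95 * sin(a), 1.05 * cos(a), 1.05 * sin(a),
                       col = "grey40")
    graphics::text(1.18 * cos(ang(ch, len[ch] / 2)),
                   1.18 * sin(ang(ch, len[ch] / 2)),
                   sub("chr", "", ch), cex = 0.6)
  }
  p <- spec$points
  if (nrow(p)) {
    radius <- ifelse(p$ring == "cn", 0.75 + 0.1 * pmin(p$y, 2) / 2, 0.9)
    a <- 2 * pi * p$x / total
    graphics::points(radius * cos(a), radius * sin(a),
                     col = point_colors(p), pch = 16, cex = 0.5)
  }
  if (nrow(spec$arcs)) {
    for (i in seq_len(nrow(spec$arcs))) {
      a1 <- ang(spec$arcs$chrom_a[i], spec$arcs$pos_a[i])
      a2 <- ang(spec$arcs$chrom_b[i], spec$arcs$pos_b[i])
      t <- seq(0, 1, length.out = 50)
      ## quadratic bezier through the center region
      x <- (1 - t)^2 * 0.7 * cos(a1) + t^2 * 0.7 * cos(a2)
      y <- (1 - t)^2 * 0.7 * sin(a1) + t^2 * 0.7 * sin(a2)
      inter <- spec$arcs$chrom_a[i] != spec$arcs$chrom_b[i]
      graphics::lines(x, y, col = if (inter) "red" else "grey30")
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
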