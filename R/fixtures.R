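## Synthetic panel fixtures: BEDs, tumor/normal depth tables with injected
## copy-number events, small-variant and SV VCFs (CSQ strings, breakend mate
## pairs), and SNP allelic tables with LOH shifts. Everything is reproducible
## byte-for-byte from (config, seed); coordinates are small synthetic
## positions on real contig names so both genome builds exercise the same
## code paths.

#' Simulation configuration for panel fixtures
#'
#' Defaults describe a small myeloma-like tumor/normal panel: ~100x mean
#' depth, 10% multiplicative depth noise, two clonal single-copy deletions
#' (true ratio 0.5) and one single-copy gain (true ratio 1.5), a handful of
#' somatic mutations with VEP-style CSQ annotations, structural variants
#' including one reciprocal inter-chromosomal breakend pair (a
#' translocation), and germline SNPs whose tumor allele fractions shift over
#' the deleted and gained regions (tumor fraction 0.8).
#'
#' @param seed integer seed fixing every output.
#' @param n_chromosomes number of chromosomes used (chr1, chr2, ...).
#' @param genes_per_chromosome,intervals_per_gene panel layout.
#' @param base_depth mean read depth of the normal sample.
#' @param depth_cv coefficient of variation of the multiplicative log-normal
#'   depth noise, applied independently to every tumor and normal depth.
#' @param events named numeric vector `c(GENE03 = 0.5, ...)` of injected true
#'   ratios; `NULL` picks two deletions (0.5) and one gain (1.5) spread over
#'   the panel.
#' @param n_mutations,n_svs,n_snps record counts for the variant fixtures.
#' @param interchromosomal_fraction fraction of SV events that are
#'   inter-chromosomal breakend pairs (at least one when `n_svs > 0`).
#' @param tumor_fraction tumor purity used for SNP allele-fraction shifts.
#' @param blacklist_genes genes whose intervals go into a blacklist BED.
#' @param emit_log2 add a CNVKit-style `log2` ratio column to the tumor depth
#'   table (exercises the provider-ratio path).
#' @param genome `"hg38"` (default) or `"hg19"`.
#' @return a `sim_config` object.
#' @export
simulation_config <- function(seed = 1, n_chromosomes = 4,
                              genes_per_chromosome = 3, intervals_per_gene = 4,
                              base_depth = 100, depth_cv = 0.1, events = NULL,
                              n_mutations = 6, n_svs = 4, n_snps = 40,
                              interchromosomal_fraction = 0.25,
                              tumor_fraction = 0.8,
                              blacklist_genes = character(0),
                              emit_log2 = FALSE, genome = "hg38") {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 22,
            genes_per_chromosome >= 1, intervals_per_gene >= 1,
            base_depth > 0, depth_cv >= 0,
            tumor_fraction > 0, tumor_fraction <= 1)
  n_genes <- n_chromosomes * genes_per_chromosome
  if (is.null(events)) {
    gene_name <- function(i) sprintf("GENE%02d", i)
    picks <- unique(pmax(1L, floor(n_genes * c(1, 2, 3) / 4)))
    events <- stats::setNames(c(0.5, 0.5, 1.5)[seq_along(picks)],
                              gene_name(picks))
  }
  if (any(events <= 0)) stop("event true ratios must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 intervals_per_gene = intervals_per_gene,
                 base_depth = base_depth, depth_cv = depth_cv, events = events,
                 n_mutations = n_mutations, n_svs = n_svs, n_snps = n_snps,
                 interchromosomal_fraction = interchromosomal_fraction,
                 tumor_fraction = tumor_fraction,
                 blacklist_genes = blacklist_genes, emit_log2 = emit_log2,
                 genome = genome),
            class = "sim_config")
}

## Panel layout as a data frame (one row per interval).
panel_layout <- function(config) {
  rows <- list()
  gene_i <- 0L
  for (c_i in seq_len(config$n_chromosomes)) {
    for (g_i in seq_len(config$genes_per_chromosome)) {
      gene_i <- gene_i + 1L
      gene <- sprintf("GENE%02d", gene_i)
      gstart <- 1000000L * g_i
      k <- seq_len(config$intervals_per_gene)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste0("chr", c_i), start = gstart + (k - 1L) * 1000L,
        end = gstart + (k - 1L) * 1000L + 200L, gene = gene,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Generate the panel BED files
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return named list of paths: `targets`, `groups`, and `blacklist` (`NULL`
#'   when no blacklist genes are configured).
#' @export
generate_panel <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- panel_layout(config)
  targets <- file.path(dir, "targets.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", lay$chrom, lay$start, lay$end, lay$gene),
             targets)
  per_gene <- split(lay, lay$gene)
  per_gene <- per_gene[order(vapply(per_gene, function(d) min(which(lay$gene == d$gene[1])), 1L))]
  groups <- file.path(dir, "groups.bed")
  writeLines(vapply(per_gene, function(d) {
    sprintf("%s\t%d\t%d\t%s", d$chrom[1], min(d$start), max(d$end), d$gene[1])
  }, character(1)), groups)
  blacklist <- NULL
  if (length(config$blacklist_genes)) {
    bl <- lay[lay$gene %in% config$blacklist_genes, , drop = FALSE]
    if (nrow(bl) == 0) stop("blacklist_genes name no panel gene", call. = FALSE)
    blacklist <- file.path(dir, "blacklist.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", bl$chrom, bl$start, bl$end, bl$gene),
               blacklist)
  }
  list(targets = targets, groups = groups, blacklist = blacklist)
}

## Mean-one multiplicative log-normal noise with the given CV.
noise_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate tumor/normal depth tables with injected copy-number events
#'
#' Normal depths are `base_depth` times independent mean-one log-normal noise
#' (CV `depth_cv`); tumor depths are `base_depth * true_ratio` times noise,
#' rescaled so the autosome-mean tumor depth stays at `base_depth` — i.e. the
#' only systematic tumor/normal difference is the injected events, and with
#' `depth_cv = 0` the normalized ratio recovers every true ratio exactly.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return named list of paths: `tumor`, `normal`, `truth` (per-interval true
#'   ratios).
#' @export
generate_depths <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  lay <- panel_layout(config)
  truth <- rep(1, nrow(lay))
  hit <- match(lay$gene, names(config$events))
  truth[!is.na(hit)] <- unname(config$events)[hit[!is.na(hit)]]

  n <- nrow(lay)
  normal <- config$base_depth * noise_multiplier(n, config$depth_cv)
  auto <- is_autosome(lay$chrom)
  tumor <- config$base_depth * truth / mean(truth[auto]) *
    noise_multiplier(n, config$depth_cv)

  base_cols <- data.frame(chromosome = lay$chrom, start = lay$start,
                          end = lay$end, gene = lay$gene,
                          stringsAsFactors = FALSE)
  normal_tab <- cbind(base_cols, depth = sprintf("%.6f", normal))
  tumor_tab <- cbind(base_cols, depth = sprintf("%.6f", tumor))
  if (config$emit_log2) {
    t_nf <- mean(tumor[auto]); n_nf <- mean(normal[auto])
    r <- (tumor / t_nf) / (normal / n_nf)
    tumor_tab$log2 <- sprintf("%.6f", log2(r))
  }
  list(tumor = write_tsv(tumor_tab, file.path(dir, "tumor_depths.tsv")),
       normal = write_tsv(normal_tab, file.path(dir, "normal_depths.tsv")),
       truth = write_tsv(cbind(base_cols, true_ratio = truth),
                         file.path(dir, "truth.tsv")))
}

vcf_header <- function(config, extra = character(0), samples = NULL) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chroms),
    extra,
    paste(cols, collapse = "\t"))
}

.CSQ_FIELDS <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "Gene",
                 "HGVSc", "HGVSp", "Protein_position", "Amino_acids")

#' Generate variant fixtures: small-variant VCF, SV VCF, SNP allelic table
#'
#' The small-variant VCF mixes PASS, `"."` and failing FILTER values in a
#' fixed cycle (3 PASS : 1 "." : 1 fail) and carries VEP-style CSQ
#' annotations for all but the last record (which exercises the raw-INFO
#' path). The SV VCF contains intra-chromosomal DEL/DUP/INV records plus
#' reciprocal inter-chromosomal breakend mate pairs with MATEID (patterned on
#' an IgH-style translocation between two panel chromosomes). The SNP table
#' holds germline-het and hom sites whose tumor allele fractions are shifted
#' over the injected deletion and gain events according to the configured
#' tumor fraction.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return named list of paths: `small_variants`, `svs`, `snps`.
#' @export
generate_vcfs <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  lay <- panel_layout(config)

  ## ---- small variants ----
  nm <- config$n_mutations
  pick <- sort(sample(nrow(lay), nm, replace = nm > nrow(lay)))
  pos <- lay$start[pick] + 1L + (seq_len(nm) * 37L) %% 150L
  refalt <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  ra <- refalt[(seq_len(nm) - 1L) %% 4L + 1L]
  filt <- rep(c("PASS", "PASS", "PASS", ".", "LowEVS"), length.out = nm)
  cons <- rep(c("missense_variant", "stop_gained", "synonymous_variant",
                "frameshift_variant"), length.out = nm)
  aa <- rep(c("R/G", "Q/*", "L", "K/T"), length.out = nm)
  info <- character(nm)
  for (i in seq_len(nm)) {
    if (i == nm && nm > 1) { info[i] <- "SOMATIC"; next }  # raw-INFO record
    hgvsp <- if (i %% 3 == 0) "" else sprintf("p.Xaa%dYaa", i * 7)
    csq <- paste(c(ra[[i]][2], cons[i], "MODERATE", lay$gene[pick[i]],
                   sprintf("ENSG%011d", pick[i]),
                   sprintf("c.%dA>G", i * 11), hgvsp, as.character(i * 7),
                   aa[i]), collapse = "|")
    info[i] <- paste0("SOMATIC;CSQ=", csq)
  }
  mut_lines <- sprintf("%s\t%d\tmut_%d\t%s\t%s\t.\t%s\t%s",
                       lay$chrom[pick], pos, seq_len(nm),
                       vapply(ra, `[`, "", 1L), vapply(ra, `[`, "", 2L),
                       filt, info)
  small_path <- file.path(dir, "small_variants.vcf")
  writeLines(c(vcf_header(config, c(
    '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic event">',
    sprintf('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations from Ensembl VEP. Format: %s">',
            paste(.CSQ_FIELDS, collapse = "|")))),
    mut_lines), small_path)

  ## ---- structural variants ----
  n_sv <- config$n_svs
  k_inter <- if (n_sv > 0) max(1L, round(n_sv * config$interchromosomal_fraction))
             else 0L
  n_intra <- n_sv - k_inter
  sv_lines <- character(0)
  intra_types <- rep(c("DEL", "DUP", "INV"), length.out = max(n_intra, 0))
  intra_filt <- rep(c("PASS", "PASS", "MinQUAL"), length.out = max(n_intra, 0))
  for (i in seq_len(n_intra)) {
    row <- lay[((i * 5L) %% nrow(lay)) + 1L, ]
    sv_lines <- c(sv_lines, sprintf(
      "%s\t%d\tsv_%d\tN\t<%s>\t.\t%s\tSVTYPE=%s;END=%d",
      row$chrom, row$start + 10L, i, intra_types[i], intra_filt[i],
      intra_types[i], row$end + 5000L))
  }
  chroms <- unique(lay$chrom)
  for (j in seq_len(k_inter)) {
    ca <- chroms[(2L * j - 2L) %% length(chroms) + 1L]
    cb <- chroms[(2L * j - 1L) %% length(chroms) + 1L]
    if (ca == cb) cb <- chroms[(match(ca, chroms)) %% length(chroms) + 1L]
    pa <- 1500000L + j * 100L
    pb <- 2500000L + j * 100L
    ida <- sprintf("bnd_%da", j); idb <- sprintf("bnd_%db", j)
    sv_lines <- c(sv_lines,
      sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s",
              ca, pa, ida, cb, pb, idb),
      sprintf("%s\t%d\t%s\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=%s",
              cb, pb, idb, ca, pa, ida))
  }
  sv_path <- file.path(dir, "structural_variants.vcf")
  writeLines(c(vcf_header(config, c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=MATEID,Number=.,Type=String,Description="ID of mate breakend">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">')),
    sv_lines), sv_path)

  ## ---- SNP allelic table ----
  ns <- config$n_snps
  f <- config$tumor_fraction
  si <- sort(sample(nrow(lay), ns, replace = ns > nrow(lay)))
  spos <- lay$start[si] + 1L + (seq_len(ns) * 53L) %% 190L
  truth <- rep(1, nrow(lay))
  hit <- match(lay$gene, names(config$events))
  truth[!is.na(hit)] <- unname(config$events)[hit[!is.na(hit)]]
  het <- stats::runif(ns) < 0.7
  dp_n <- stats::rpois(ns, config$base_depth)
  dp_t <- stats::rpois(ns, config$base_depth)
  p_n <- ifelse(het, 0.5, ifelse(stats::runif(ns) < 0.5, 0.005, 0.995))
  p_t <- p_n
  for (k in which(het)) {
    r <- truth[si[k]]
    if (r < 1) {                      # single-copy deletion: one allele lost
      c_alt <- sample(0:1, 1)
      p_t[k] <- ((1 - f) + f * c_alt) / (2 * (1 - f) + f)
    } else if (r > 1) {               # single-copy gain: one allele duplicated
      c_alt <- sample(1:2, 1)
      p_t[k] <- ((1 - f) + f * c_alt) / (2 * (1 - f) + 3 * f)
    }
  }
  alt_n <- stats::rbinom(ns, dp_n, p_n)
  alt_t <- stats::rbinom(ns, dp_t, p_t)
  snp_tab <- data.frame(chrom = lay$chrom[si], pos = spos,
                        normal_ref = dp_n - alt_n, normal_alt = alt_n,
                        tumor_ref = dp_t - alt_t, tumor_alt = alt_t,
                        stringsAsFactors = FALSE)
  ## one off-panel site to exercise the flag
  snp_tab <- rbind(snp_tab, data.frame(
    chrom = "chr1", pos = 50L, normal_ref = 48L, normal_alt = 52L,
    tumor_ref = 50L, tumor_alt = 50L))
  snp_path <- write_tsv(snp_tab, file.path(dir, "snps.tsv"))

  list(small_variants = small_path, svs = sv_path, snps = snp_path)
}

#' Generate a complete fixture set
#'
#' Runs [generate_panel()], [generate_depths()] and [generate_vcfs()] into one
#' directory and writes the per-interval truth table alongside.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return named list of all fixture paths.
#' @export
generate_fixture_set <- function(config, dir) {
  c(generate_panel(config, dir), generate_depths(config, dir),
    generate_vcfs(config, dir))
}
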