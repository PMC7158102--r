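# Shared test helpers: literal mini-fixtures written in code, a full
# generated fixture set, and an independent brute-force ratio oracle.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A tiny 3-chromosome panel written literally (not via the generator).
tiny_targets_bed <- function() {
  write_lines_tmp(c(
    "chr1\t100\t200\tALPHA",
    "chr1\t300\t400\tALPHA",
    "chr1\t500\t600\tBETA",
    "chr2\t100\t200\tGAMMA",
    "2\t300\t400\tGAMMA",          # bare chromosome name on purpose
    "chrX\t100\t200\tDELTA"
  ), ".bed")
}

tiny_groups_bed <- function() {
  write_lines_tmp(c(
    "chr1\t100\t400\tALPHA",
    "chr1\t500\t600\tBETA",
    "chr2\t100\t400\tGAMMA",
    "chrX\t100\t200\tDELTA"
  ), ".bed")
}

tiny_db <- function(blacklist = NULL, path = ":memory:") {
  create_panel_db(path, "tiny", "hg38", "test",
                  tiny_targets_bed(), tiny_groups_bed(), blacklist)
}

# Depth table text for the tiny panel, depths given in target order.
tiny_depth_table <- function(depths, extra_cols = NULL) {
  hdr <- "chromosome\tstart\tend\tdepth"
  coords <- c("chr1\t100\t200", "chr1\t300\t400", "chr1\t500\t600",
              "chr2\t100\t200", "chr2\t300\t400", "chrX\t100\t200")
  lines <- paste0(coords[seq_along(depths)], "\t", depths)
  if (!is.null(extra_cols)) {
    hdr <- paste0(hdr, "\t", extra_cols$name)
    lines <- paste0(lines, "\t", extra_cols$values)
  }
  write_lines_tmp(c(hdr, lines), ".tsv")
}

# Minimal hand-written VCFs.
mini_vcf_header <- function(extra = character(0)) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>", "##contig=<ID=chr2>", "##contig=<ID=chr4>",
    "##contig=<ID=chr14>", "##contig=<ID=chr17>",
    extra,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

mini_small_vcf <- function() {
  csq_hdr <- paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description=',
                    '"Consequence annotations from Ensembl VEP. Format: ',
                    'Allele|Consequence|SYMBOL|HGVSc|HGVSp">')
  write_lines_tmp(c(mini_vcf_header(csq_hdr), c(
    "chr1\t150\tm1\tA\tG\t.\tPASS\tCSQ=G|missense_variant|ALPHA|c.1A>G|p.K1E",
    "chr1\t350\tm2\tC\tT\t.\t.\tCSQ=T|stop_gained|ALPHA|c.9C>T|p.Q3*",
    "chr2\t150\tm3\tG\tA\t.\tLowEVS\tCSQ=A|synonymous_variant|GAMMA|c.33G>A|",
    "chr2\t160\tm4\tT\tA,C\t.\tPASS\tCSQ=A|missense_variant|GAMMA|c.40T>A|p.W14R,C|missense_variant|GAMMA|c.40T>C|p.W14S",
    "chr17\t999\tm5\tG\tC\t.\tPASS\t."
  )), ".vcf")
}

# SV VCF patterned on a t(4;14)-style translocation plus intra events.
mini_sv_vcf <- function() {
  write_lines_tmp(c(mini_vcf_header(c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=MATEID,Number=.,Type=String,Description="Mate">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INV,Description="Inversion">')), c(
    "chr17\t1000\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000",
    "chr17\t8000\tinv1\tN\t<INV>\t.\tMinQUAL\tSVTYPE=INV;END=9500",
    "chr4\t1871000\tt1a\tN\tN[chr14:105740000[\t.\tPASS\tSVTYPE=BND;MATEID=t1b",
    "chr14\t105740000\tt1b\tN\t]chr4:1871000]N\t.\tPASS\tSVTYPE=BND;MATEID=t1a",
    "chr2\t700\tbad1\tN\tN[garbled\t.\tPASS\tSVTYPE=BND"
  )), ".vcf")
}

# Full generated fixture set loaded into a fresh in-memory database.
fixture_db <- function(seed = 1, config = simulation_config(seed = seed),
                       sample_id = "S1", path = ":memory:") {
  dir <- tempfile("fixtures")
  paths <- generate_fixture_set(config, dir)
  db <- create_panel_db(path, "fixture", config$genome, "test",
                        paths$targets, paths$groups, paths$blacklist)
  register_sample(db, sample_id)
  import_depths(db, sample_id, paths$tumor, paths$normal)
  suppressWarnings(import_small_variants(db, sample_id, paths$small_variants))
  suppressWarnings(import_structural_variants(db, sample_id, paths$svs))
  import_snp_records(db, sample_id, paths$snps)
  list(db = db, paths = paths, config = config, sample_id = sample_id,
       truth = utils::read.delim(paths$truth))
}

# Independent brute-force ratio oracle: plain arithmetic on depth vectors,
# sharing no code with the engine.
oracle_ratios <- function(chrom, tumor, normal, norm_chroms) {
  sel <- chrom %in% norm_chroms
  t_nf <- sum(tumor[sel]) / sum(sel)
  n_nf <- sum(normal[sel]) / sum(sel)
  out <- numeric(length(tumor))
  for (i in seq_along(out)) {
    out[i] <- (tumor[i] / t_nf) / (normal[i] / n_nf)
  }
  out
}

expect_setequal_df <- function(a, b, cols) {
  expect_setequal(do.call(paste, a[cols]), do.call(paste, b[cols]))
}
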