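test_that("import_depths matches rows to panel intervals exactly", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  tum <- tiny_depth_table(c(10, 20, 30, 40, 50, 60))
  nor <- tiny_depth_table(c(10, 10, 10, 10, 10, 10))
  expect_equal(import_depths(db, "S1", tum, nor), 12)
  expect_equal(panel_samples(db)$has_depths, 1)

  # one extra off-panel row: stored count unchanged, skip warned
  extra <- write_lines_tmp(c(readLines(tum), "chr2\t900\t950\t7"), ".tsv")
  expect_warning(n <- import_depths(db, "S1", extra, nor), "1 off-panel")
  expect_equal(n, 12)

  # coordinates shifted by one: nothing matches -> hard error
  shifted <- write_lines_tmp(c("chromosome\tstart\tend\tdepth",
                               "chr1\t101\t201\t10"), ".tsv")
  expect_error(import_depths(db, "S1", shifted, nor), "right panel")

  # negative depth row rejected with diagnostic
  neg <- write_lines_tmp(c("chromosome\tstart\tend\tdepth",
                           "chr1\t100\t200\t-5", "chr1\t300\t400\t8"), ".tsv")
  ok <- write_lines_tmp(c("chromosome\tstart\tend\tdepth",
                          "chr1\t300\t400\t8"), ".tsv")
  expect_warning(import_depths(db, "S1", neg, ok), "negative depth")
  expect_equal(nrow(sample_depths(db, "S1")), 2)
})

test_that("depth re-import is idempotent and ratio/log2 columns are stored", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  tum <- tiny_depth_table(c(10, 20, 30, 40, 50, 60),
                          extra_cols = list(name = "log2",
                                            values = c(-1, 0, 1, 0.5, 0, 2)))
  nor <- tiny_depth_table(rep(10, 6))
  import_depths(db, "S1", tum, nor)
  n1 <- nrow(sample_depths(db, "S1"))
  import_depths(db, "S1", tum, nor)
  expect_equal(nrow(sample_depths(db, "S1")), n1)

  d <- sample_depths(db, "S1")
  expect_equal(d$precomputed_ratio[d$role == "tumor"],
               2^c(-1, 0, 1, 0.5, 0, 2))

  lin <- tiny_depth_table(rep(10, 6),
                          extra_cols = list(name = "ratio",
                                            values = c(0.5, 1, 2, 1, 1, 1)))
  import_depths(db, "S1", lin, nor)
  d <- sample_depths(db, "S1")
  expect_equal(d$precomputed_ratio[d$role == "tumor"], c(0.5, 1, 2, 1, 1, 1))
})

test_that("small variants keep FILTER verbatim and split multi-allelics", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  n <- import_small_variants(db, "S1", mini_small_vcf())
  expect_equal(n, 6)  # 5 records, one with two ALTs
  rows <- mutation_table(db, "S1", show_failed = TRUE)
  expect_setequal(rows$filter, c("PASS", ".", "LowEVS"))
  expect_equal(sum(rows$filter == "PASS"), 4)

  split <- rows[rows$pos == 160, ]
  expect_equal(nrow(split), 2)
  expect_setequal(split$alt, c("A", "C"))
  # per-ALT CSQ entry matched by Allele
  expect_equal(split$protein_change[split$alt == "A"], "p.W14R")
  expect_equal(split$protein_change[split$alt == "C"], "p.W14S")

  ann <- rows[rows$pos == 150 & rows$chrom == "chr1", ]
  expect_equal(ann$gene_symbol, "ALPHA")
  expect_equal(ann$consequence, "missense_variant")
  expect_equal(ann$codon_change, "c.1A>G")

  # record without CSQ: empty annotation, raw INFO carried
  raw <- rows[rows$chrom == "chr17", ]
  expect_equal(raw$gene_symbol, "")
  expect_equal(raw$has_annotation, 0L)
  expect_equal(raw$raw_info, ".")

  # idempotent re-import
  import_small_variants(db, "S1", mini_small_vcf())
  expect_equal(nrow(mutation_table(db, "S1", show_failed = TRUE)), 6)
})

test_that("a VCF without a CSQ header imports without annotations", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  vcf <- write_lines_tmp(c(mini_vcf_header(),
                           "chr1\t150\tv1\tA\tG\t.\tPASS\t."), ".vcf")
  expect_equal(import_small_variants(db, "S1", vcf), 1)
  rows <- mutation_table(db, "S1")
  expect_equal(rows$gene_symbol, "")
  expect_equal(rows$has_annotation, 0L)
})

test_that("parse_csq maps named subfields and skips malformed entries", {
  got <- parse_csq("A|missense_variant|TP53",
                   c("Allele", "Consequence", "SYMBOL"))
  expect_length(got, 1)
  expect_equal(got[[1]]$gene_symbol, "TP53")
  expect_equal(got[[1]]$consequence, "missense_variant")
  expect_equal(got[[1]]$protein_change, "")

  two <- parse_csq("A|m|G1,T|s|G2", c("Allele", "Consequence", "SYMBOL"))
  expect_equal(vapply(two, `[[`, "", "gene_symbol"), c("G1", "G2"))

  empty_sym <- parse_csq("A|m|", c("Allele", "Consequence", "SYMBOL"))
  expect_equal(empty_sym[[1]]$gene_symbol, "")

  # HGVSp fallback to Amino_acids + Protein_position
  fb <- parse_csq("A|m|G|c.1A>G||12|R/Q",
                  c("Allele", "Consequence", "SYMBOL", "HGVSc", "HGVSp",
                    "Protein_position", "Amino_acids"))
  expect_equal(fb[[1]]$protein_change, "p.R12Q")
  expect_equal(fb[[1]]$codon_change, "c.1A>G")

  expect_warning(bad <- parse_csq("A|b|c|d", c("Allele", "Consequence")),
                 "skipped")
  expect_length(bad, 0)
})

test_that("parse_csq inverts a CSQ writer over randomized annotations", {
  fmt <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "HGVSc", "HGVSp",
           "Protein_position", "Amino_acids")
  alphabet <- c(LETTERS, letters, 0:9, ".", ">", "_")
  set.seed(404)
  rand_field <- function() {
    if (runif(1) < 0.2) "" else
      paste(sample(alphabet, sample(1:8, 1), replace = TRUE), collapse = "")
  }
  for (i in 1:50) {
    n_entries <- sample(1:3, 1)
    truth <- replicate(n_entries, vapply(fmt, function(f) rand_field(), ""),
                       simplify = FALSE)
    csq <- paste(vapply(truth, paste, "", collapse = "|"), collapse = ",")
    got <- parse_csq(csq, fmt)
    expect_length(got, n_entries)
    for (k in seq_len(n_entries)) {
      expect_equal(got[[k]]$gene_symbol, unname(truth[[k]]["SYMBOL"]))
      expect_equal(got[[k]]$consequence, unname(truth[[k]]["Consequence"]))
      expect_equal(got[[k]]$codon_change, unname(truth[[k]]["HGVSc"]))
      if (nzchar(truth[[k]]["HGVSp"])) {
        expect_equal(got[[k]]$protein_change, unname(truth[[k]]["HGVSp"]))
      }
      expect_equal(got[[k]]$extras$IMPACT, unname(truth[[k]]["IMPACT"]))
      expect_equal(got[[k]]$extras$Allele, unname(truth[[k]]["Allele"]))
    }
  }
})

test_that("structural variants parse breakend partners and flags", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  expect_warning(n <- import_structural_variants(db, "S1", mini_sv_vcf()),
                 "unparseable BND")
  expect_equal(n, 5)
  rows <- sv_table(db, "S1", show_failed = TRUE)

  del <- rows[rows$record_id == "del1", ]
  expect_equal(del$sv_type, "DEL")
  expect_equal(del$end, 5000)
  expect_false(del$is_interchromosomal)

  t1a <- rows[rows$record_id == "t1a", ]
  expect_equal(t1a$partner_chrom, "chr14")
  expect_equal(t1a$partner_pos, 105740000)
  expect_true(t1a$is_interchromosomal)
  t1b <- rows[rows$record_id == "t1b", ]
  expect_equal(t1b$partner_chrom, "chr4")
  expect_true(t1b$is_interchromosomal)

  inv <- rows[rows$record_id == "inv1", ]
  expect_equal(inv$filter, "MinQUAL")

  bad <- rows[rows$record_id == "bad1", ]
  expect_equal(bad$partner_unparsed, 1L)
  expect_true(is.na(bad$partner_chrom))
  expect_false(bad$is_interchromosomal)

  suppressWarnings(import_structural_variants(db, "S1", mini_sv_vcf()))
  expect_equal(nrow(sv_table(db, "S1", show_failed = TRUE)), 5)
})

test_that("SNP records import from tables with count conservation", {
  db <- tiny_db()
  on.exit(close_panel_db(db))
  register_sample(db, "S1")
  tab <- write_lines_tmp(c(
    "chrom\tpos\tnormal_ref\tnormal_alt\ttumor_ref\ttumor_alt",
    "chr1\t150\t10\t10\t18\t2",
    "chr1\t350\t20\t0\t20\t1",
    "chr2\t150\t12\t11\t3\t20",
    "chr2\t9999\t10\t10\t10\t10",   # off-panel
    "chrX\t150\t10\t10\tNA\t5"      # missing depth -> skipped
  ), ".tsv")
  expect_warning(n <- import_snp_records(db, "S1", tab), "missing allele")
  expect_equal(n, 4)
  rows <- snp_records(db, "S1")
  expect_equal(nrow(rows), 4)
  expect_equal(rows$on_panel, c(1L, 1L, 1L, 0L))
  expect_equal(rows$normal_ref[1], 10)
  expect_equal(rows$normal_alt[1], 10)
})
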