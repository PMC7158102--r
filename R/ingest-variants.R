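## VCF ingest: small variants (with VEP CSQ extraction), structural variants
## (including breakend partners), and SNP allelic-depth records.
##
## Parsing goes through VariantAnnotation::readVcf; this file only adds the
## panel-specific pieces: CSQ subfield extraction, breakend bracket-ALT
## partner parsing, multi-allelic splitting, and raw INFO retention.

read_vcf_file <- function(path, genome) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  suppressWarnings(VariantAnnotation::readVcf(path, genome = genome))
}

## Raw INFO column (field 8) of each record, in file order, so the original
## annotation text can be displayed when no CSQ is present.
read_vcf_info_column <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  vapply(strsplit(body, "\t", fixed = TRUE),
         function(f) if (length(f) >= 8) f[8] else "", character(1))
}

vcf_filter_status <- function(vcf) {
  f <- VariantAnnotation::filt(vcf)
  f[is.na(f) | !nzchar(f)] <- "."
  f
}

## CSQ subfield names declared in the VCF header ("... Format: A|B|C"),
## or NULL when the file carries no CSQ annotation.
csq_format_from_header <- function(vcf) {
  ih <- VariantAnnotation::info(VariantAnnotation::header(vcf))
  if (!"CSQ" %in% rownames(ih)) return(NULL)
  desc <- ih["CSQ", "Description"]
  fmt <- sub(".*Format:\\s*", "", desc)
  fmt <- gsub("[\"']", "", fmt)
  strsplit(fmt, "|", fixed = TRUE)[[1]]
}

empty_annotation <- function() {
  list(gene_symbol = "", consequence = "", protein_change = "",
       codon_change = "", extras = list())
}

#' Parse an Ensembl-VEP CSQ INFO value
#'
#' Splits a CSQ value into its comma-separated per-transcript entries and each
#' entry into the pipe-separated subfields named by the VCF header. The fields
#' a reviewer needs are lifted out by their VEP names: `SYMBOL` (gene symbol),
#' `Consequence`, `HGVSp` (protein change; falls back to
#' `Amino_acids`/`Protein_position` as `p.<ref><pos><alt>` when `HGVSp` is
#' absent), `HGVSc` (codon change). All remaining subfields are kept verbatim
#' in `extras`. Subfields absent from an entry stay empty strings, never
#' invented.
#'
#' @param info_value the CSQ string (entries separated by `,`).
#' @param csq_format character vector of subfield names from the header's
#'   `Format:` declaration.
#' @return list of annotations, one per entry, each a list with elements
#'   `gene_symbol`, `consequence`, `protein_change`, `codon_change`, `extras`.
#'   Entries whose subfield count exceeds the header's are skipped with a
#'   warning.
#' @export
#' @examples
#' parse_csq("A|missense_variant|TP53", c("Allele", "Consequence", "SYMBOL"))
parse_csq <- function(info_value, csq_format) {
  stopifnot(is.character(csq_format), length(csq_format) >= 1)
  if (is.na(info_value) || !nzchar(info_value)) return(list())
  entries <- strsplit(info_value, ",", fixed = TRUE)[[1]]
  out <- vector("list", length(entries))
  keep <- logical(length(entries))
  core <- c("SYMBOL", "Consequence", "HGVSp", "HGVSc",
            "Protein_position", "Amino_acids")
  for (i in seq_along(entries)) {
    sub <- strsplit(entries[i], "|", fixed = TRUE)[[1]]
    if (length(sub) > length(csq_format)) {
      warning("CSQ entry has ", length(sub), " subfields but header declares ",
              length(csq_format), "; entry skipped", call. = FALSE)
      next
    }
    sub <- c(sub, rep("", length(csq_format) - length(sub)))
    names(sub) <- csq_format
    ann <- empty_annotation()
    get <- function(k) if (k %in% names(sub)) sub[[k]] else ""
    ann$gene_symbol <- get("SYMBOL")
    ann$consequence <- get("Consequence")
    ann$protein_change <- get("HGVSp")
    if (!nzchar(ann$protein_change)) {
      aa <- get("Amino_acids"); pp <- get("Protein_position")
      if (nzchar(aa) && nzchar(pp)) {
        parts <- strsplit(aa, "/", fixed = TRUE)[[1]]
        ann$protein_change <- if (length(parts) == 2) {
          paste0("p.", parts[1], pp, parts[2])
        } else {
          paste0("p.", pp, aa)
        }
      }
    }
    ann$codon_change <- get("HGVSc")
    ann$extras <- as.list(sub[setdiff(names(sub), core)])
    out[[i]] <- ann
    keep[i] <- TRUE
  }
  out[keep]
}

#' Import small variants for a sample from a VCF
#'
#' Stores one row per ALT allele (multi-allelic records are split), keeping
#' the FILTER value verbatim. When the file carries Ensembl-VEP CSQ
#' annotations the gene symbol, consequence, protein and codon changes are
#' extracted (first CSQ entry whose Allele matches the row's ALT, else the
#' first entry); otherwise annotation columns stay empty and the raw INFO text
#' is retained for display. Re-importing replaces the sample's previous rows.
#'
#' @param db a writable `panel_db` handle.
#' @param sample_id a registered sample.
#' @param vcf path to a VCF 4.x file.
#' @return invisibly, the number of variant rows stored.
#' @export
import_small_variants <- function(db, sample_id, vcf) {
  con <- db_con(db)
  stop_unless_sample(db, sample_id)
  genome <- panel_info(db)$reference_genome
  v <- read_vcf_file(vcf, genome)
  raw_info <- read_vcf_info_column(vcf)
  rr <- SummarizedExperiment::rowRanges(v)
  alt_list <- VariantAnnotation::alt(v)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  idx <- rep(seq_along(n_alt), n_alt)
  alt <- as.character(unlist(alt_list))
  fmt <- csq_format_from_header(v)
  csq <- if (!is.null(fmt)) {
    cl <- VariantAnnotation::info(v)$CSQ
    vapply(as.list(cl), function(x) paste(x, collapse = ","), character(1))
  }

  rows <- data.frame(
    sample_id = sample_id,
    chrom = normalize_chromosome(as.character(GenomeInfoDb::seqnames(rr)))[idx],
    pos = BiocGenerics::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(v))[idx],
    alt = alt,
    filter = vcf_filter_status(v)[idx],
    gene_symbol = "", consequence = "", protein_change = "", codon_change = "",
    extras = "", raw_info = raw_info[idx], has_annotation = 0L,
    stringsAsFactors = FALSE)

  if (!is.null(fmt)) {
    allele_at <- match("Allele", fmt)
    for (r in seq_len(nrow(rows))) {
      anns <- parse_csq(csq[idx[r]], fmt)
      if (length(anns) == 0) next
      pick <- 1L
      if (!is.na(allele_at)) {
        alleles <- vapply(strsplit(strsplit(csq[idx[r]], ",", fixed = TRUE)[[1]],
                                   "|", fixed = TRUE),
                          function(x) if (length(x) >= allele_at) x[allele_at] else "",
                          character(1))
        hit <- which(alleles == rows$alt[r])
        if (length(hit)) pick <- hit[1]
        if (pick > length(anns)) pick <- 1L
      }
      a <- anns[[pick]]
      rows$gene_symbol[r] <- a$gene_symbol
      rows$consequence[r] <- a$consequence
      rows$protein_change[r] <- a$protein_change
      rows$codon_change[r] <- a$codon_change
      rows$extras[r] <- as.character(
        jsonlite::toJSON(a$extras, auto_unbox = TRUE))
      rows$has_annotation[r] <- 1L
    }
  }

  DBI::dbExecute(con, "DELETE FROM small_variants WHERE sample_id = :s",
                 params = list(s = sample_id))
  db_insert(con, "small_variants", rows)
  set_sample_flag(db, sample_id, "has_small_variants")
  invisible(nrow(rows))
}

## Parse one breakend bracket ALT ("A[chr8:128000000[", "]chr4:1000]T", ...).
## Returns list(chrom, pos) or NULL when the notation is unparseable.
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt,
                               perl = TRUE))[[1]]
  if (length(m) != 3) return(NULL)
  ch <- tryCatch(normalize_chromosome(m[2]), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(chrom = ch, pos = as.integer(m[3]))
}

#' Import structural variants for a sample from a VCF
#'
#' Stores one row per record. Breakend (BND) records get their partner
#' chromosome and position parsed from the bracket ALT notation; both mates of
#' a pair are stored (plot builders deduplicate them). A BND whose ALT cannot
#' be parsed is stored without a partner and flagged. `is_interchromosomal` is
#' true exactly when a parsed partner lies on a different chromosome.
#' Re-importing replaces the sample's previous rows.
#'
#' @param db a writable `panel_db` handle.
#' @param sample_id a registered sample.
#' @param vcf path to a VCF with SVTYPE INFO keys (Manta-style).
#' @return invisibly, the number of SV rows stored.
#' @export
import_structural_variants <- function(db, sample_id, vcf) {
  con <- db_con(db)
  stop_unless_sample(db, sample_id)
  genome <- panel_info(db)$reference_genome
  v <- read_vcf_file(vcf, genome)
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  n <- length(rr)
  if (!"SVTYPE" %in% names(info)) {
    stop("SV VCF lacks the SVTYPE INFO key: ", vcf, call. = FALSE)
  }
  svtype <- as.character(info$SVTYPE)
  end <- if ("END" %in% names(info)) as.integer(info$END) else rep(NA_integer_, n)
  mate <- if ("MATEID" %in% names(info)) {
    m <- info$MATEID
    if (is.list(m) || inherits(m, "List")) {
      vapply(as.list(m), function(x) if (length(x)) as.character(x[1]) else NA_character_,
             character(1))
    } else as.character(m)
  } else rep(NA_character_, n)
  alt_list <- VariantAnnotation::alt(v)
  alt1 <- vapply(as.list(alt_list),
                 function(x) if (length(x)) as.character(x[1]) else "",
                 character(1))

  rows <- data.frame(
    sample_id = sample_id, record_id = names(rr),
    chrom = normalize_chromosome(as.character(GenomeInfoDb::seqnames(rr))),
    pos = BiocGenerics::start(rr), end = end, sv_type = svtype,
    partner_chrom = NA_character_, partner_pos = NA_integer_,
    mate_id = mate, filter = vcf_filter_status(v),
    is_interchromosomal = 0L, partner_unparsed = 0L,
    stringsAsFactors = FALSE)

  for (i in which(svtype == "BND")) {
    p <- parse_bnd_alt(alt1[i])
    if (is.null(p)) {
      rows$partner_unparsed[i] <- 1L
      warning("unparseable BND ALT '", alt1[i], "' in ", vcf,
              "; record stored without partner", call. = FALSE)
    } else {
      rows$partner_chrom[i] <- p$chrom
      rows$partner_pos[i] <- p$pos
      rows$is_interchromosomal[i] <- as.integer(p$chrom != rows$chrom[i])
    }
  }

  DBI::dbExecute(con, "DELETE FROM svs WHERE sample_id = :s",
                 params = list(s = sample_id))
  db_insert(con, "svs", rows)
  set_sample_flag(db, sample_id, "has_svs")
  invisible(nrow(rows))
}

#' Import SNP allelic-depth records for a sample
#'
#' Accepts either a tab-separated table with columns
#' `chrom`(/`chromosome`), `pos`, `normal_ref`, `normal_alt`, `tumor_ref`,
#' `tumor_alt`, or a VCF carrying the `AD` FORMAT field for a normal and a
#' tumor sample column. Rows missing any allele depth are skipped with a
#' warning. Sites outside every panel target are kept but flagged off-panel.
#' Re-importing replaces the sample's previous rows.
#'
#' @param db a writable `panel_db` handle.
#' @param sample_id a registered sample.
#' @param source path to the table or VCF.
#' @param normal_sample,tumor_sample VCF sample column names (VCF input only);
#'   default to the first and second columns.
#' @return invisibly, the number of SNP records stored.
#' @export
import_snp_records <- function(db, sample_id, source,
                               normal_sample = NULL, tumor_sample = NULL) {
  con <- db_con(db)
  stop_unless_sample(db, sample_id)
  if (grepl("\\.vcf(\\.gz)?$", source)) {
    genome <- panel_info(db)$reference_genome
    v <- read_vcf_file(source, genome)
    g <- VariantAnnotation::geno(v)
    if (!"AD" %in% names(g)) stop("VCF lacks the AD FORMAT field: ", source,
                                  call. = FALSE)
    ad <- g$AD
    samp <- colnames(ad)
    if (is.null(normal_sample)) normal_sample <- samp[1]
    if (is.null(tumor_sample)) tumor_sample <- samp[2]
    if (!all(c(normal_sample, tumor_sample) %in% samp)) {
      stop("VCF sample columns not found: ",
           paste(setdiff(c(normal_sample, tumor_sample), samp), collapse = ", "),
           call. = FALSE)
    }
    rr <- SummarizedExperiment::rowRanges(v)
    pull <- function(s) t(vapply(seq_len(nrow(ad)), function(i) {
      x <- ad[[i, s]]
      if (length(x) >= 2 && !anyNA(x[1:2])) as.integer(x[1:2])
      else c(NA_integer_, NA_integer_)
    }, integer(2)))
    nad <- pull(normal_sample); tad <- pull(tumor_sample)
    tab <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(rr)),
      pos = BiocGenerics::start(rr),
      normal_ref = nad[, 1], normal_alt = nad[, 2],
      tumor_ref = tad[, 1], tumor_alt = tad[, 2], stringsAsFactors = FALSE)
  } else {
    if (!file.exists(source)) stop("SNP table not found: ", source, call. = FALSE)
    tab <- utils::read.delim(source, check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if ("chromosome" %in% names(tab) && !"chrom" %in% names(tab)) {
      tab$chrom <- tab$chromosome
    }
    need <- c("chrom", "pos", "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
    if (!all(need %in% names(tab))) {
      stop("SNP table ", source, " must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    tab <- tab[, need]
  }
  n_read <- nrow(tab)
  complete <- stats::complete.cases(
    tab[, c("normal_ref", "normal_alt", "tumor_ref", "tumor_alt")])
  if (any(!complete)) {
    warning(sum(!complete), " SNP row(s) missing allele depths skipped from ",
            source, call. = FALSE)
  }
  tab <- tab[complete, , drop = FALSE]
  if (any(tab[, 3:6] < 0)) stop("negative allele depths in ", source, call. = FALSE)
  tab$chrom <- normalize_chromosome(tab$chrom)

  targets <- panel_targets(db)
  on_panel <- vapply(seq_len(nrow(tab)), function(i) {
    same <- targets$chrom == tab$chrom[i]
    any(same & targets$start < tab$pos[i] & tab$pos[i] <= targets$end)
  }, logical(1))

  DBI::dbExecute(con, "DELETE FROM snps WHERE sample_id = :s",
                 params = list(s = sample_id))
  db_insert(con, "snps", data.frame(
    sample_id = sample_id, tab, on_panel = as.integer(on_panel),
    stringsAsFactors = FALSE))
  set_sample_flag(db, sample_id, "has_snps")
  invisible(nrow(tab))
}

#' SNP allelic records for one sample
#' @param db a `panel_db` handle.
#' @param sample_id a registered sample.
#' @export
snp_records <- function(db, sample_id) {
  stop_unless_sample(db, sample_id)
  DBI::dbGetQuery(db_con(db),
    "SELECT * FROM snps WHERE sample_id = :s ORDER BY rowid",
    params = list(s = sample_id))
}
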