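## Mutation and structural-variant table views.
##
## The viewer's filter rule: a record passes iff its FILTER column is exactly
## "PASS" or "." (semicolon-joined multi-value FILTERs count as failed). The
## default tables show only passing records; "show failed" reveals all.

passes_filter <- function(filter_status) {
  filter_status %in% c("PASS", ".")
}

#' Mutation table for a sample
#'
#' @param db a `panel_db` handle.
#' @param sample_id a registered sample with imported small variants.
#' @param chromosome optional chromosome restriction.
#' @param show_failed include records whose FILTER is neither `PASS` nor `.`.
#' @return data frame sorted by (chromosome, position, alt) with annotation
#'   columns (empty when the VCF carried no CSQ; `raw_info` holds the original
#'   INFO text) and `passed_filter`.
#' @export
mutation_table <- function(db, sample_id, chromosome = NULL,
                           show_failed = FALSE) {
  stop_unless_sample(db, sample_id)
  rows <- DBI::dbGetQuery(db_con(db),
    "SELECT chrom, pos, ref, alt, gene_symbol, consequence, protein_change,
            codon_change, extras, raw_info, has_annotation, filter
     FROM small_variants WHERE sample_id = :s",
    params = list(s = sample_id))
  rows$passed_filter <- passes_filter(rows$filter)
  if (!is.null(chromosome)) {
    ch <- tryCatch(normalize_chromosome(chromosome), error = function(e) NA)
    rows <- rows[!is.na(ch) & rows$chrom %in% ch, , drop = FALSE]
  }
  if (!show_failed) rows <- rows[rows$passed_filter, , drop = FALSE]
  if (nrow(rows)) {
    rows <- rows[order(chromosome_rank(rows$chrom), rows$pos, rows$alt), ]
  }
  rownames(rows) <- NULL
  rows
}

#' Structural-variant table for a sample
#'
#' Filter and sorting contract as in [mutation_table()]. A breakend row
#' matches a chromosome restriction when either its own or its partner
#' chromosome matches, so inter-chromosomal events are discoverable from both
#' ends.
#'
#' @inheritParams mutation_table
#' @return data frame with SV type, partner coordinates,
#'   `is_interchromosomal` and `passed_filter`.
#' @export
sv_table <- function(db, sample_id, chromosome = NULL, show_failed = FALSE) {
  stop_unless_sample(db, sample_id)
  rows <- DBI::dbGetQuery(db_con(db),
    "SELECT record_id, chrom, pos, \"end\" AS end, sv_type, partner_chrom,
            partner_pos, mate_id, filter, is_interchromosomal, partner_unparsed
     FROM svs WHERE sample_id = :s",
    params = list(s = sample_id))
  rows$passed_filter <- passes_filter(rows$filter)
  rows$is_interchromosomal <- as.logical(rows$is_interchromosomal)
  if (!is.null(chromosome)) {
    ch <- tryCatch(normalize_chromosome(chromosome), error = function(e) NA)
    hit <- !is.na(ch) &
      (rows$chrom %in% ch |
         (!is.na(rows$partner_chrom) & rows$partner_chrom %in% ch))
    rows <- rows[hit, , drop = FALSE]
  }
  if (!show_failed) rows <- rows[rows$passed_filter, , drop = FALSE]
  if (nrow(rows)) {
    rows <- rows[order(chromosome_rank(rows$chrom), rows$pos, rows$sv_type), ]
  }
  rownames(rows) <- NULL
  rows
}
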