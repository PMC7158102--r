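## Depth-table ingest.
##
## Tables are tab-separated with CNVKit-style columns: chromosome (or chrom),
## start, end, depth; an optional precomputed ratio column ("ratio", linear)
## or log2 column ("log2", exponentiated to linear at ingest) is stored in
## precomputed_ratio. Rows are matched to panel targets exactly on
## (chromosome, start, end) after name normalization -- the table is expected
## to have been produced against the same BED as the panel.

read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  chrom_col <- intersect(c("chromosome", "chrom"), names(tab))[1]
  need <- c(chrom_col, "start", "end", "depth")
  if (is.na(chrom_col) || !all(need %in% names(tab))) {
    stop("depth table ", path,
         " must have columns chromosome/chrom, start, end, depth",
         call. = FALSE)
  }
  out <- data.frame(chrom = normalize_chromosome(tab[[chrom_col]]),
                    start = as.integer(tab$start), end = as.integer(tab$end),
                    depth = as.numeric(tab$depth),
                    precomputed_ratio = NA_real_, stringsAsFactors = FALSE)
  if ("ratio" %in% names(tab)) {
    out$precomputed_ratio <- as.numeric(tab$ratio)
  } else if ("log2" %in% names(tab)) {
    out$precomputed_ratio <- 2^as.numeric(tab$log2)
  }
  out
}

import_one_role <- function(db, sample_id, path, role) {
  con <- db_con(db)
  tab <- read_depth_table(path)
  n_read <- nrow(tab)
  neg <- !is.na(tab$depth) & tab$depth < 0
  if (any(neg)) {
    warning(sum(neg), " row(s) with negative depth rejected from ", path,
            call. = FALSE)
    tab <- tab[!neg, , drop = FALSE]
  }
  targets <- panel_targets(db)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  idx <- match(key(tab), key(targets))
  n_skip <- sum(is.na(idx))
  if (all(is.na(idx))) {
    stop("no row of ", path, " matches a panel interval; ",
         "is this table from the right panel?", call. = FALSE)
  }
  if (n_skip > 0) {
    warning(n_skip, " off-panel row(s) skipped from ", path, call. = FALSE)
  }
  keep <- !is.na(idx)
  db_insert(con, "depths", data.frame(
    sample_id = sample_id, role = role, target_id = targets$target_id[idx[keep]],
    depth = tab$depth[keep], precomputed_ratio = tab$precomputed_ratio[keep]))
  c(stored = sum(keep), skipped = n_skip + sum(neg), read = n_read + sum(neg))
}

#' Import tumor and normal depth tables for a sample
#'
#' Stores one tumor and one normal depth record per panel interval matched in
#' the tables. Matching is exact on (chromosome, start, end); off-panel rows
#' are skipped with a warning, and matching nothing at all is an error (wrong
#' panel). Re-importing replaces the sample's previous depth records.
#'
#' @param db a writable `panel_db` handle.
#' @param sample_id a registered sample.
#' @param tumor_table,normal_table tab-separated depth tables with columns
#'   chromosome/chrom, start, end, depth and optionally ratio or log2.
#' @return invisibly, the number of depth records stored (tumor + normal).
#' @export
import_depths <- function(db, sample_id, tumor_table, normal_table) {
  con <- db_con(db)
  stop_unless_sample(db, sample_id)
  DBI::dbExecute(con, "DELETE FROM depths WHERE sample_id = :s",
                 params = list(s = sample_id))
  nt <- import_one_role(db, sample_id, tumor_table, "tumor")
  nn <- import_one_role(db, sample_id, normal_table, "normal")
  set_sample_flag(db, sample_id, "has_depths")
  invisible(unname(nt["stored"] + nn["stored"]))
}

#' Depth records for one sample
#'
#' @param db a `panel_db` handle.
#' @param sample_id a registered sample.
#' @return data frame with target coordinates, `role`, `depth`,
#'   `precomputed_ratio`.
#' @export
sample_depths <- function(db, sample_id) {
  stop_unless_sample(db, sample_id)
  DBI::dbGetQuery(db_con(db),
    "SELECT d.sample_id, d.role, d.target_id, t.chrom, t.start,
            t.\"end\" AS end, t.label, d.depth, d.precomputed_ratio
     FROM depths d JOIN targets t ON t.target_id = d.target_id
     WHERE d.sample_id = :s ORDER BY d.role, d.target_id",
    params = list(s = sample_id))
}
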