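## SQLite-backed panel database: schema, creation, and queries.
##
## One single-file database per panel. Coordinates are stored exactly as BED
## gives them (0-based half-open); VCF-derived positions are 1-based and
## converted at ingest. Chromosome names are stored normalized ("chr" prefix).

.SCHEMA <- c(
  "CREATE TABLE panel_meta (
     name TEXT NOT NULL, reference_genome TEXT NOT NULL,
     pipeline_version TEXT NOT NULL, created TEXT NOT NULL)",
  "CREATE TABLE targets (
     target_id INTEGER PRIMARY KEY, chrom TEXT NOT NULL,
     start INTEGER NOT NULL, \"end\" INTEGER NOT NULL, label TEXT)",
  "CREATE TABLE gene_groups (
     group_id INTEGER PRIMARY KEY, group_name TEXT NOT NULL UNIQUE)",
  "CREATE TABLE group_regions (
     group_id INTEGER NOT NULL, chrom TEXT NOT NULL,
     start INTEGER NOT NULL, \"end\" INTEGER NOT NULL)",
  "CREATE TABLE group_members (
     group_id INTEGER NOT NULL, target_id INTEGER NOT NULL,
     UNIQUE (group_id, target_id))",
  "CREATE TABLE blacklist (
     chrom TEXT NOT NULL, start INTEGER NOT NULL, \"end\" INTEGER NOT NULL,
     label TEXT)",
  "CREATE TABLE samples (
     sample_id TEXT PRIMARY KEY, has_depths INTEGER NOT NULL DEFAULT 0,
     has_small_variants INTEGER NOT NULL DEFAULT 0,
     has_svs INTEGER NOT NULL DEFAULT 0, has_snps INTEGER NOT NULL DEFAULT 0)",
  "CREATE TABLE depths (
     sample_id TEXT NOT NULL, role TEXT NOT NULL, target_id INTEGER NOT NULL,
     depth REAL NOT NULL, precomputed_ratio REAL)",
  "CREATE TABLE small_variants (
     variant_id INTEGER PRIMARY KEY, sample_id TEXT NOT NULL,
     chrom TEXT NOT NULL, pos INTEGER NOT NULL,
     ref TEXT NOT NULL, alt TEXT NOT NULL, filter TEXT NOT NULL,
     gene_symbol TEXT, consequence TEXT, protein_change TEXT,
     codon_change TEXT, extras TEXT, raw_info TEXT,
     has_annotation INTEGER NOT NULL DEFAULT 0)",
  "CREATE TABLE svs (
     sv_id INTEGER PRIMARY KEY, sample_id TEXT NOT NULL, record_id TEXT,
     chrom TEXT NOT NULL, pos INTEGER NOT NULL, \"end\" INTEGER,
     sv_type TEXT NOT NULL, partner_chrom TEXT, partner_pos INTEGER,
     mate_id TEXT, filter TEXT NOT NULL,
     is_interchromosomal INTEGER NOT NULL DEFAULT 0,
     partner_unparsed INTEGER NOT NULL DEFAULT 0)",
  "CREATE TABLE snps (
     sample_id TEXT NOT NULL, chrom TEXT NOT NULL, pos INTEGER NOT NULL,
     normal_ref INTEGER NOT NULL, normal_alt INTEGER NOT NULL,
     tumor_ref INTEGER NOT NULL, tumor_alt INTEGER NOT NULL,
     on_panel INTEGER NOT NULL DEFAULT 1)"
)

## Bulk insert via one prepared statement (much lighter than dbWriteTable).
db_insert <- function(con, table, df) {
  if (nrow(df) == 0) return(invisible(0L))
  cols <- names(df)
  sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", table,
                 paste(sprintf("\"%s\"", cols), collapse = ","),
                 paste(sprintf(":%s", cols), collapse = ","))
  DBI::dbExecute(con, sql, params = as.list(df))
}

new_panel_db <- function(con, path) {
  structure(list(con = con, path = path), class = "panel_db")
}

db_con <- function(db) {
  stopifnot(inherits(db, "panel_db"))
  if (!DBI::dbIsValid(db$con)) stop("database connection is closed", call. = FALSE)
  db$con
}

#' Create a new panel database
#'
#' Creates a single-file SQLite database holding the panel definition: target
#' intervals, gene-group annotations and an optional blacklist of unreliable
#' regions. Samples are registered and imported afterwards; a fresh database
#' contains zero samples.
#'
#' @param path filesystem path for the database file (`":memory:"` allowed for
#'   a transient in-memory database).
#' @param name display name of the panel/database.
#' @param genome reference genome build, `"hg19"` or `"hg38"`.
#' @param pipeline_version free-text version tag of the upstream pipeline.
#' @param targets_bed BED file (0-based half-open) of captured intervals;
#'   column 4, when present, is the interval label (typically the gene).
#' @param groups_bed BED file of gene-group regions; column 4 is the group
#'   name. A target belongs to a group when it overlaps one of the group's
#'   regions by at least 1 bp.
#' @param blacklist_bed optional BED of blacklisted regions, hidden from views
#'   and excluded from normalization.
#' @param overwrite replace an existing file (default `FALSE`: refuse).
#' @return a `panel_db` handle (keep it; it holds the open connection).
#' @export
create_panel_db <- function(path, name, genome, pipeline_version = "unversioned",
                            targets_bed, groups_bed, blacklist_bed = NULL,
                            overwrite = FALSE) {
  if (!genome %in% c("hg19", "hg38")) {
    stop("unsupported reference genome '", genome,
         "'; supported values are hg19, hg38", call. = FALSE)
  }
  targets <- read_bed(targets_bed)
  if (nrow(targets) == 0L) stop("targets BED is empty: ", targets_bed, call. = FALSE)
  targets$label[is.na(targets$label)] <- ""
  targets <- sort_intervals(targets)
  groups <- read_bed(groups_bed)
  if (anyNA(groups$label)) {
    stop("groups BED requires a group name in column 4: ", groups_bed,
         call. = FALSE)
  }
  blacklist <- if (is.null(blacklist_bed)) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  } else {
    read_bed(blacklist_bed)
  }

  if (!identical(path, ":memory:")) {
    if (file.exists(path)) {
      if (!overwrite) {
        stop("database file already exists: ", path,
             " (use overwrite = TRUE to replace it)", call. = FALSE)
      }
      unlink(path)
    }
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ok <- FALSE
  on.exit(if (!ok && !identical(path, ":memory:")) {
    DBI::dbDisconnect(con); unlink(path)
  })
  for (stmt in .SCHEMA) DBI::dbExecute(con, stmt)
  DBI::dbExecute(con,
    "INSERT INTO panel_meta (name, reference_genome, pipeline_version, created)
     VALUES (:n, :g, :p, :c)",
    params = list(n = name, g = genome, p = pipeline_version,
                  c = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  targets$target_id <- seq_len(nrow(targets))
  db_insert(con, "targets",
                    targets[, c("target_id", "chrom", "start", "end", "label")])
  group_names <- unique(groups$label)
  if (length(group_names)) {
    db_insert(con, "gene_groups",
      data.frame(group_id = seq_along(group_names), group_name = group_names))
    groups$group_id <- match(groups$label, group_names)
    db_insert(con, "group_regions",
                      groups[, c("group_id", "chrom", "start", "end")])
    members <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      hit <- targets$chrom == groups$chrom[i] &
        intervals_overlap(targets$start, targets$end,
                          groups$start[i], groups$end[i])
      if (!any(hit)) return(NULL)
      data.frame(group_id = groups$group_id[i],
                 target_id = targets$target_id[hit])
    }))
    if (!is.null(members)) {
      members <- unique(members)
      db_insert(con, "group_members", members)
    }
  }
  if (nrow(blacklist)) {
    db_insert(con, "blacklist",
                      blacklist[, c("chrom", "start", "end", "label")])
  }
  ok <- TRUE
  on.exit()
  new_panel_db(con, path)
}

#' Open an existing panel database
#'
#' @param path path to a database file created by [create_panel_db()].
#' @return a `panel_db` handle.
#' @export
open_panel_db <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  if (!"panel_meta" %in% DBI::dbListTables(con)) {
    DBI::dbDisconnect(con)
    stop("not a panel database (no panel_meta table): ", path, call. = FALSE)
  }
  new_panel_db(con, path)
}

#' Close a panel database handle
#' @param db a `panel_db` handle.
#' @export
close_panel_db <- function(db) {
  if (DBI::dbIsValid(db$con)) DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' Panel metadata (name, genome, pipeline version)
#' @param db a `panel_db` handle.
#' @return one-row data frame.
#' @export
panel_info <- function(db) {
  DBI::dbGetQuery(db_con(db), "SELECT * FROM panel_meta")
}

#' All target intervals of the panel (unfiltered, genomic order)
#' @param db a `panel_db` handle.
#' @export
panel_targets <- function(db) {
  DBI::dbGetQuery(db_con(db),
    "SELECT target_id, chrom, start, \"end\" AS end, label FROM targets
     ORDER BY target_id")
}

#' Blacklisted regions of the panel
#' @param db a `panel_db` handle.
#' @export
panel_blacklist <- function(db) {
  DBI::dbGetQuery(db_con(db),
    "SELECT chrom, start, \"end\" AS end, label FROM blacklist")
}

#' Gene-group membership of panel targets
#'
#' @param db a `panel_db` handle.
#' @return data frame with one row per (group, member target):
#'   `group_name`, `target_id`, `chrom`, `start`, `end`, `label`. Groups with
#'   no member targets appear with `NA` target columns.
#' @export
panel_groups <- function(db) {
  DBI::dbGetQuery(db_con(db),
    "SELECT g.group_name, m.target_id, t.chrom, t.start, t.\"end\" AS end,
            t.label
     FROM gene_groups g
     LEFT JOIN group_members m ON m.group_id = g.group_id
     LEFT JOIN targets t ON t.target_id = m.target_id
     ORDER BY g.group_id, m.target_id")
}

#' Registered samples and their data-presence flags
#' @param db a `panel_db` handle.
#' @export
panel_samples <- function(db) {
  DBI::dbGetQuery(db_con(db), "SELECT * FROM samples ORDER BY rowid")
}

#' Register a sample in the database
#'
#' @param db a writable `panel_db` handle.
#' @param sample_id unique sample identifier.
#' @return invisibly, the sample row as a one-row data frame.
#' @export
register_sample <- function(db, sample_id) {
  con <- db_con(db)
  exists <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) AS n FROM samples WHERE sample_id = :s",
    params = list(s = sample_id))$n
  if (exists > 0) stop("sample already registered: ", sample_id, call. = FALSE)
  DBI::dbExecute(con, "INSERT INTO samples (sample_id) VALUES (:s)",
                 params = list(s = sample_id))
  invisible(DBI::dbGetQuery(con, "SELECT * FROM samples WHERE sample_id = :s",
                            params = list(s = sample_id)))
}

stop_unless_sample <- function(db, sample_id) {
  n <- DBI::dbGetQuery(db_con(db),
    "SELECT COUNT(*) AS n FROM samples WHERE sample_id = :s",
    params = list(s = sample_id))$n
  if (n == 0) stop("unknown sample: ", sample_id, call. = FALSE)
}

set_sample_flag <- function(db, sample_id, flag) {
  DBI::dbExecute(db_con(db),
    sprintf("UPDATE samples SET %s = 1 WHERE sample_id = :s", flag),
    params = list(s = sample_id))
}

#' List databases named in a YAML registry
#'
#' The registry (conventionally `config.yml`) is a YAML mapping of display
#' names to database file paths; only databases listed there are surfaced to
#' the viewer. A top-level `databases:` key wrapping the mapping is also
#' accepted.
#'
#' @param config path to the YAML file.
#' @return data frame with columns `name`, `path`, `missing` (TRUE when the
#'   file does not exist), in file order.
#' @export
list_databases <- function(config) {
  if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
  parsed <- tryCatch(yaml::read_yaml(config), error = function(e) {
    stop("could not parse config ", config, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(parsed$databases)) parsed <- parsed$databases
  if (length(parsed) == 0L) {
    return(data.frame(name = character(), path = character(),
                      missing = logical(), stringsAsFactors = FALSE))
  }
  if (is.null(names(parsed)) || any(!nzchar(names(parsed)))) {
    stop("config ", config, " must be a mapping of database names to paths",
         call. = FALSE)
  }
  data.frame(name = names(parsed),
             path = vapply(parsed, as.character, character(1)),
             missing = !file.exists(vapply(parsed, as.character, character(1))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Query panel target intervals
#'
#' Returns the panel's captured intervals, optionally restricted to one
#' chromosome. Intervals overlapping a blacklist region by at least 1 bp are
#' hidden unless `include_blacklisted = TRUE` (the viewer's "show blacklist
#' genes" switch).
#'
#' @param db a `panel_db` handle.
#' @param chromosome optional chromosome name (any accepted spelling); an
#'   unknown or absent chromosome yields an empty result, not an error.
#' @param include_blacklisted include intervals overlapping the blacklist.
#' @return data frame of intervals sorted by (chromosome, start, end, label).
#' @export
query_intervals <- function(db, chromosome = NULL, include_blacklisted = FALSE) {
  targets <- panel_targets(db)
  if (!is.null(chromosome)) {
    ch <- tryCatch(normalize_chromosome(chromosome), error = function(e) NA)
    targets <- targets[!is.na(ch) & targets$chrom %in% ch, , drop = FALSE]
  }
  if (!include_blacklisted && nrow(targets)) {
    bl <- panel_blacklist(db)
    targets <- targets[!overlaps_any(targets, bl), , drop = FALSE]
  }
  sort_intervals(targets)
}

#' @export
print.panel_db <- function(x, ...) {
  info <- panel_info(x)
  cat(sprintf("panel database '%s' (%s, pipeline %s)\n  path: %s\n",
              info$name, info$reference_genome, info$pipeline_version, x$path))
  n <- function(tbl) DBI::dbGetQuery(db_con(x),
    sprintf("SELECT COUNT(*) AS n FROM %s", tbl))$n
  cat(sprintf("  %d targets, %d gene groups, %d blacklist regions, %d samples\n",
              n("targets"), n("gene_groups"), n("blacklist"), n("samples")))
  invisible(x)
}
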