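# Homology signal: best-hit E-value of a query against the positive
# training database, and its piecewise log transform onto [-3, 200].
#
# Two interchangeable backends supply hits: a precomputed tabular backend
# (the default everywhere in tests: fully deterministic, no external
# binary) and an external BLAST+ backend that builds a protein database
# from the positive training set and runs blastp with tabular output.

#' Piecewise log-transform of a best-hit E-value
#'
#' Maps an E-value onto the bounded score used in score fusion:
#' 200 when `Ev <= 1e-200`; `-log10(Ev)` when `1e-200 < Ev < 1e3`;
#' -3 when `Ev >= 1e3` or no hit was found (`NA`).
#'
#' @param ev Numeric vector of E-values (> 0), `NA` meaning no hit.
#' @return Numeric vector in `[-3, 200]`.
#' @export
#' @examples
#' transform_pev(c(1e-250, 1e-2, NA))
transform_pev <- function(ev) {
  stopifnot(is.numeric(ev) | is.logical(ev))
  ev <- as.numeric(ev)
  if (any(!is.na(ev) & ev <= 0)) abort("E-values must be positive")
  out <- ifelse(is.na(ev) | ev >= 1e3, -3,
                ifelse(ev <= 1e-200, 200, -log10(ev)))
  out
}

#' Precomputed-hits homology backend
#'
#' @param hits A tibble/data frame with columns `query`, `subject`,
#'   `evalue`, or a path to a BLAST tabular (outfmt 6 style) TSV read with
#'   [read_blast_tsv()].
#' @param ... Passed to [read_blast_tsv()] when `hits` is a path.
#' @return A homology backend object.
#' @export
homology_backend_tsv <- function(hits, ...) {
  if (is.character(hits) && length(hits) == 1) hits <- read_blast_tsv(hits, ...)
  stopifnot(is.data.frame(hits), all(c("query", "subject", "evalue") %in% names(hits)))
  structure(list(type = "tsv", hits = as_tibble(hits)), class = "homology_backend")
}

#' Read BLAST tabular output
#'
#' @param path Path to a tab-separated hit table without header (BLAST
#'   `-outfmt 6` style).
#' @param query_col,subject_col,evalue_col 1-based column indices; the
#'   defaults `1, 2, 11` match outfmt 6. For a plain 3-column table use
#'   `evalue_col = 3`.
#' @return Tibble with columns `query`, `subject`, `evalue`.
#' @export
read_blast_tsv <- function(path, query_col = 1, subject_col = 2, evalue_col = 11) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < max(query_col, subject_col, evalue_col)) {
    abort(sprintf("hit table has %d columns but evalue_col = %d", ncol(tab), evalue_col))
  }
  tibble(query = tab[[query_col]], subject = tab[[subject_col]],
         evalue = as.numeric(tab[[evalue_col]]))
}

#' External BLAST+ homology backend
#'
#' Builds a protein BLAST database from the positive training records in a
#' temporary directory and runs `blastp -outfmt 6` on the queries.
#'
#' @param blastp,makeblastdb Executable names or paths.
#' @param evalue_max E-value reporting ceiling passed to blastp.
#' @return A homology backend object.
#' @export
homology_backend_blast <- function(blastp = "blastp", makeblastdb = "makeblastdb",
                                   evalue_max = 1e3) {
  if (Sys.which(blastp) == "" || Sys.which(makeblastdb) == "") {
    abort(paste0("BLAST+ executables not found on PATH; use the precomputed ",
                 "hit-table backend (homology_backend_tsv) instead"))
  }
  structure(list(type = "blast", blastp = blastp, makeblastdb = makeblastdb,
                 evalue_max = evalue_max), class = "homology_backend")
}

backend_hits <- function(backend, queries, db) {
  if (backend$type == "tsv") return(backend$hits)
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dbf <- file.path(dir, "db.fasta")
  qf <- file.path(dir, "q.fasta")
  write_fasta(db, dbf)
  write_fasta(queries, qf)
  system2(backend$makeblastdb, c("-in", dbf, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(dir, "hits.tsv")
  system2(backend$blastp, c("-query", qf, "-db", dbf, "-outfmt", "6",
                            "-evalue", format(backend$evalue_max, scientific = TRUE),
                            "-out", out),
          stdout = FALSE, stderr = FALSE)
  if (!file.exists(out) || file.size(out) == 0) {
    return(tibble(query = character(0), subject = character(0), evalue = numeric(0)))
  }
  read_blast_tsv(out)
}

#' Best-hit E-values and pEv for a set of queries
#'
#' For each query, takes the lowest E-value over all hits against the
#' database, excluding self-hits (identical query and subject id), and
#' attaches the transformed score from [transform_pev()]. Queries without
#' any hit get `best_ev = NA` and `pev = -3`.
#'
#' @param queries Dataset tibble of query records.
#' @param db Dataset tibble forming the search database (the positive
#'   training set).
#' @param backend A backend from [homology_backend_tsv()] or
#'   [homology_backend_blast()].
#' @return Tibble with columns `query_id`, `best_ev`, `pev`, one row per
#'   query in input order.
#' @export
best_hit_all <- function(queries, db, backend) {
  validate_dataset(queries, "queries")
  validate_dataset(db, "db")
  stopifnot(inherits(backend, "homology_backend"))
  if (nrow(db) == 0) abort("database is empty")
  hits <- backend_hits(backend, queries, db)
  hits <- filter(hits, query %in% queries$id, subject %in% db$id,
                 query != subject, !is.na(evalue))
  best <- vapply(split(hits$evalue, hits$query), min, numeric(1))
  ev <- unname(best[match(queries$id, names(best))])
  tibble(query_id = queries$id, best_ev = ev, pev = transform_pev(ev))
}

#' Best hit for a single query
#'
#' @param query One-row dataset tibble (or a tibble from which the first
#'   row is taken).
#' @inheritParams best_hit_all
#' @return One-row tibble with `query_id`, `best_ev`, `pev`.
#' @export
best_hit <- function(query, db, backend) {
  best_hit_all(head(query, 1), db, backend)
}

#' List database homologs of a query under an E-value ceiling
#'
#' The reporting filter used for annotating predictions with database
#' homologs (default ceiling 1e-4); separate from best-hit extraction.
#'
#' @inheritParams best_hit_all
#' @param evalue_max Report only hits with `evalue < evalue_max`.
#' @return Tibble of hits (`query`, `subject`, `evalue`), best first.
#' @export
homolog_hits <- function(queries, db, backend, evalue_max = 1e-4) {
  hits <- backend_hits(backend, queries, db)
  hits <- filter(hits, query %in% queries$id, subject %in% db$id,
                 query != subject, evalue < evalue_max)
  arrange(hits, query, evalue)
}
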