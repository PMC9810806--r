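#' @keywords internal
"_PACKAGE"

#' Taxonomic ranks used throughout the package
#'
#' Lineages are stored at six ranks from kingdom to genus; missing levels
#' carry the sentinel `"UNASSIGNED"`.
#'
#' @format Character vector of rank names, most to least inclusive.
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Sentinel for a missing taxonomic assignment
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Validate an OTU count table
#'
#' An OTU table is an integer matrix of non-negative read counts with
#' samples in rows and OTUs in columns; both dimensions carry unique
#' identifiers.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly coerced to integer storage, if valid; otherwise an
#'   error is thrown describing the violated invariant.
#' @export
validate_otu_table <- function(x) {
  if (!is.matrix(x)) stop("OTU table must be a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("OTU table needs at least 1 sample and 1 OTU", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("OTU table must have sample and OTU identifiers", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("OTU table contains non-finite counts", call. = FALSE)
  if (any(x < 0)) stop("OTU table contains negative counts", call. = FALSE)
  if (any(x != round(x)))
    stop("OTU table counts must be integers", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

#' Read an OTU count table from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row holds OTU ids and
#' whose first column holds sample ids (the sample-centric orientation used
#' throughout). Set `transpose = TRUE` for the OTU-as-rows dialect common in
#' amplicon pipelines.
#'
#' @param path file path.
#' @param transpose logical; input has OTUs as rows.
#' @return validated integer matrix (samples x OTUs).
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  raw <- read_tsv_matrix(path, what = "OTU table")
  if (transpose) raw <- t(raw)
  validate_otu_table(raw)
}

#' Write an OTU count table to TSV
#'
#' @param x validated OTU table.
#' @param path output path.
#' @param id_column header label of the sample-id column.
#' @export
write_otu_table <- function(x, path, id_column = "sample_id") {
  x <- validate_otu_table(x)
  write_tsv_matrix(x, path, id_column)
}

# shared TSV matrix reader: first column = row ids, header = column ids
read_tsv_matrix <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop(what, ": no samples in ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  if (length(col_ids) < 1L) stop(what, ": no data columns", call. = FALSE)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, length(body), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    if (length(cells) != length(col_ids))
      stop(what, ": row '", row_ids[[i]], "' has ", length(cells),
           " cells, expected ", length(col_ids), call. = FALSE)
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1L]]
      stop(what, ": malformed numeric cell at row '", row_ids[[i]],
           "', column '", col_ids[[bad]], "': '", cells[[bad]], "'",
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  vals
}

write_tsv_matrix <- function(x, path, id_column) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(c(rownames(x)[[i]], format(x[i, ], scientific = FALSE,
                                                trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Build a taxonomy map from lineage strings
#'
#' Lineages are semicolon-delimited, ordered kingdom to genus; QIIME-style
#' rank prefixes (`k__`, `p__`, ...) are stripped. Missing trailing ranks
#' and empty fields are padded with [UNASSIGNED]. No rank below an
#' unassigned rank is retained (assignment gaps are not allowed).
#'
#' @param otu_ids character vector of OTU identifiers.
#' @param lineages character vector of lineage strings, same length.
#' @return data.frame with columns `otu_id` and the six [TAX_RANKS].
#' @export
taxonomy_map <- function(otu_ids, lineages) {
  stopifnot(length(otu_ids) == length(lineages))
  if (anyDuplicated(otu_ids)) {
    dup <- unique(otu_ids[duplicated(otu_ids)])
    for (d in dup) {
      if (length(unique(lineages[otu_ids == d])) > 1L)
        stop("OTU '", d, "' listed twice with conflicting lineages",
             call. = FALSE)
    }
    keep <- !duplicated(otu_ids)
    otu_ids <- otu_ids[keep]
    lineages <- lineages[keep]
  }
  parts <- strsplit(lineages, ";", fixed = TRUE)
  mat <- matrix(UNASSIGNED, length(otu_ids), length(TAX_RANKS),
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[kpcofgs]__", "", p)
    p[p == "" | is.na(p)] <- UNASSIGNED
    p <- p[seq_len(min(length(p), length(TAX_RANKS)))]
    # truncate at the first unassigned rank: nothing below it is usable
    gap <- which(p == UNASSIGNED)
    if (length(gap)) p[seq_along(p) >= gap[[1L]]] <- UNASSIGNED
    mat[i, seq_along(p)] <- p
  }
  out <- data.frame(otu_id = otu_ids, mat, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a taxonomy map from TSV
#'
#' Two tab-separated columns: OTU id and semicolon-delimited lineage. A
#' header line is detected (first field `otu_id` or similar) and skipped.
#'
#' @param path file path.
#' @return taxonomy data.frame (see [taxonomy_map]).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("taxonomy: empty file ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(cells[[1L]][[1L]]) %in% c("otu_id", "otu", "#otu id"))
    cells <- cells[-1L]
  if (!length(cells)) stop("taxonomy: no records in ", path, call. = FALSE)
  ids <- vapply(cells, `[[`, character(1L), 1L)
  lin <- vapply(cells, function(x) if (length(x) > 1L) x[[2L]] else "",
                character(1L))
  taxonomy_map(ids, lin)
}

#' Write a taxonomy map to TSV
#' @param tax taxonomy data.frame.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  lin <- apply(tax[TAX_RANKS], 1L, paste, collapse = ";")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("otu_id\tlineage", con)
  writeLines(paste(tax$otu_id, lin, sep = "\t"), con)
  invisible(path)
}

#' Lineage at a given rank, for a set of OTUs
#' @param tax taxonomy data.frame.
#' @param otu_ids OTU ids to look up (must all be present).
#' @param rank one of [TAX_RANKS].
#' @return character vector of names (possibly [UNASSIGNED]).
#' @export
lineage_at <- function(tax, otu_ids, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  idx <- match(otu_ids, tax$otu_id)
  if (anyNA(idx))
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(otu_ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  tax[[rank]][idx]
}

SEASONS <- c("Dec", "Mar", "Jun", "Sep")
COMPARTMENTS <- c("gut", "water")

#' Environmental variables measured on water samples
#' @export
ENV_VARS <- c("Temp", "DO", "pH", "Salinity", "Dep", "SD", "Chla",
              "CODMn", "TP", "NH4N", "TN")

#' Validate per-sample metadata
#'
#' A sample frame records, for each sequenced library, its site, sampling
#' season (`Dec`, `Mar`, `Jun`, `Sep`), compartment (`gut` or `water`) and,
#' for water samples, the measured environmental variables. Environmental
#' values may be absent only on gut samples (the field campaign measures
#' the water column, not the gut).
#'
#' @param meta data.frame with columns `sample_id`, `site`, `season`,
#'   `compartment` and optionally environmental columns.
#' @return the validated data.frame.
#' @export
validate_sample_frame <- function(meta) {
  need <- c("sample_id", "site", "season", "compartment")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample frame missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  bad <- setdiff(unique(meta$compartment), COMPARTMENTS)
  if (length(bad))
    stop("compartment must be gut or water, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(meta$season), SEASONS)
  if (length(bad))
    stop("season must be one of ", paste(SEASONS, collapse = "/"),
         ", got: ", paste(bad, collapse = ", "), call. = FALSE)
  env_cols <- intersect(ENV_VARS, names(meta))
  for (v in env_cols) {
    vals <- meta[[v]]
    bad_row <- !is.na(vals) & !is.finite(vals)
    if (any(bad_row))
      stop("non-finite value in env variable ", v, call. = FALSE)
    if (any(is.na(vals) & meta$compartment == "water"))
      stop("water sample missing env variable ", v, call. = FALSE)
  }
  meta
}

#' Read sample metadata (site, season, compartment, environment) from TSV
#' @param path file path.
#' @return validated data.frame (see [validate_sample_frame]).
#' @export
read_sample_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8")
  validate_sample_frame(meta)
}

#' Write sample metadata to TSV
#' @param meta validated sample frame.
#' @param path output path.
#' @export
write_sample_frame <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the environmental matrix for a set of water samples
#'
#' @param meta validated sample frame.
#' @param sample_ids samples to extract, in order; all must be water samples
#'   with complete environmental rows (constrained ordination requires it).
#' @param vars environmental variables to keep.
#' @return numeric matrix (samples x variables).
#' @export
env_matrix <- function(meta, sample_ids, vars = ENV_VARS) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) stop("unknown sample ids in env_matrix", call. = FALSE)
  vars <- intersect(vars, names(meta))
  if (!length(vars)) stop("no environmental columns found", call. = FALSE)
  m <- as.matrix(meta[idx, vars, drop = FALSE])
  rownames(m) <- sample_ids
  storage.mode(m) <- "double"
  if (anyNA(m))
    stop("incomplete environmental rows for: ",
         paste(sample_ids[apply(is.na(m), 1L, any)], collapse = ", "),
         call. = FALSE)
  m
}
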