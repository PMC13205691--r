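# Table I/O and validation. Every table the pipeline touches is a plain
# UTF-8 tab-separated file with a header row; missing values are forbidden
# in abundance matrices (absent means 0). Sample ids join across tables by
# exact string match.

#' Abundance units understood by the package
#'
#' * `read_count` — raw (or uniquely-mapped) read counts.
#' * `relative_fraction` — per-sample fractions; each column sums to <= 1.
#' * `relative_percent` — per-sample percentages; each column sums to <= 100.
#' * `normalized_1e10` — length- and depth-normalized abundance,
#'   mapped reads / (L x N) x 1e10 (see [normalize_abundance()]).
#' @export
abundance_units <- function() {
  c("read_count", "relative_fraction", "relative_percent", "normalized_1e10")
}

#' Construct a validated taxa-by-samples abundance matrix
#'
#' The central container of the package: a nonnegative numeric matrix with
#' taxa as rows and samples as columns, carrying its unit as explicit
#' metadata so downstream thresholds (e.g. the retention filter) are always
#' interpreted in a declared unit.
#'
#' @param values numeric matrix, taxa x samples, with rownames (taxon ids)
#'   and colnames (sample ids).
#' @param unit one of [abundance_units()].
#' @return an object of class `abundance_matrix` (a numeric matrix with a
#'   `unit` attribute).
#' @export
abundance_matrix <- function(values, unit) {
  if (!is.matrix(values) || !is.numeric(values))
    pd_stop("`values` must be a numeric matrix", "schema_error")
  if (length(unit) != 1L || !unit %in% abundance_units())
    pd_stop(sprintf("unknown abundance unit: %s", paste(unit, collapse = "/")),
            "unit_error")
  tid <- rownames(values); sid <- colnames(values)
  if (is.null(tid) || is.null(sid))
    pd_stop("abundance matrix needs taxon rownames and sample colnames",
            "schema_error")
  if (anyDuplicated(tid))
    pd_stop("duplicate taxon ids in abundance matrix", "schema_error")
  if (anyDuplicated(sid))
    pd_stop("duplicate sample ids in abundance matrix", "schema_error")
  if (anyNA(values))
    pd_stop("missing values are forbidden in abundance matrices (use 0)",
            "schema_error")
  if (any(values < 0))
    pd_stop("negative values in abundance matrix", "schema_error")
  if (unit == "relative_fraction" && any(colSums(values) > 1 + 1e-9))
    pd_stop("relative_fraction columns must each sum to <= 1", "schema_error")
  if (unit == "relative_percent" && any(colSums(values) > 100 + 1e-6))
    pd_stop("relative_percent columns must each sum to <= 100", "schema_error")
  structure(values, unit = unit, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d taxa x %d samples, unit = %s\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit of an abundance matrix
#' @param m an `abundance_matrix`.
#' @export
abundance_unit <- function(m) attr(m, "unit")

#' Read an abundance matrix from a tab-separated file
#'
#' First column holds taxon ids, header row holds sample ids.
#'
#' @param path file path.
#' @param unit declared unit of the stored values (see [abundance_units()]).
#' @return a validated [abundance_matrix()].
#' @export
read_abundance <- function(path, unit) {
  if (!file.exists(path)) pd_stop(sprintf("file not found: %s", path), "io_error")
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    pd_stop(sprintf("ragged rows in %s (field counts %s)", path,
                    paste(unique(nf), collapse = ",")), "parse_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    pd_stop("abundance table needs a taxon id column plus >= 1 sample", "parse_error")
  taxa <- as.character(df[[1L]])
  sids <- names(df)[-1L]  # before subsetting: [.data.frame dedups names
  vals <- df[-1L]
  if (!all(vapply(vals, is.numeric, logical(1))))
    pd_stop(sprintf("non-numeric abundance values in %s", path), "parse_error")
  m <- as.matrix(vals)
  dimnames(m) <- list(taxa, sids)
  abundance_matrix(m, unit)
}

#' Write an abundance matrix to a tab-separated file
#' @param m an `abundance_matrix`.
#' @param path file path.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(taxon_id = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Retain taxa by relative abundance or prevalence
#'
#' A taxon is kept iff its maximum relative abundance across samples exceeds
#' `relab_threshold` OR it is detected (value > 0) in at least
#' `prevalence_fraction` of samples. Row order is preserved. The threshold
#' is interpreted in the matrix's declared relative unit.
#'
#' @param m an `abundance_matrix` in `relative_fraction` or
#'   `relative_percent` units.
#' @param relab_threshold abundance cutoff, same unit as `m` (default 0.2).
#' @param prevalence_fraction minimum detection fraction (default 0.01).
#' @param stat how the abundance disjunct summarizes a taxon across samples,
#'   `"max"` (default) or `"mean"`.
#' @return filtered `abundance_matrix`.
#' @export
filter_taxa <- function(m, relab_threshold = 0.2, prevalence_fraction = 0.01,
                        stat = c("max", "mean")) {
  stat <- match.arg(stat)
  unit <- abundance_unit(m)
  if (!unit %in% c("relative_fraction", "relative_percent"))
    pd_stop(sprintf("filter_taxa needs a relative-unit matrix, got %s", unit),
            "unit_error")
  v <- unclass(m)
  ab <- if (stat == "max") apply(v, 1L, max) else rowMeans(v)
  prev <- rowMeans(v > 0)
  keep <- (ab > relab_threshold) | (prev >= prevalence_fraction)
  abundance_matrix(v[keep, , drop = FALSE], unit)
}

# ---- sample metadata ------------------------------------------------------

#' Validate sample metadata
#'
#' Required columns: `sample_id`, `subject_id`, `group`, `day`,
#' `project_id`. `(subject_id, day)` must be unique within a project and
#' sample ids must be unique.
#'
#' @param info data.frame of sample metadata.
#' @return the validated data.frame (day coerced to integer), invisibly
#'   unchanged otherwise.
#' @export
validate_sample_info <- function(info) {
  req <- c("sample_id", "subject_id", "group", "day", "project_id")
  missing <- setdiff(req, names(info))
  if (length(missing))
    pd_stop(paste("sample metadata missing column(s):",
                  paste(missing, collapse = ", ")), "schema_error")
  if (anyDuplicated(info$sample_id))
    pd_stop("duplicate sample_id in sample metadata", "schema_error")
  day <- suppressWarnings(as.integer(info$day))
  if (anyNA(day)) pd_stop("non-integer day in sample metadata", "parse_error")
  info$day <- day
  key <- paste(info$project_id, info$subject_id, info$day, sep = "\r")
  if (anyDuplicated(key))
    pd_stop("(subject_id, day) not unique within a project", "schema_error")
  info
}

#' Read sample metadata
#' @param path tab-separated file with the [validate_sample_info()] columns.
#' @export
read_sample_info <- function(path) {
  validate_sample_info(read_tsv(path,
    c("sample_id", "subject_id", "group", "day", "project_id"), "sample metadata"))
}

#' Write sample metadata
#' @param info validated sample metadata.
#' @param path file path.
#' @export
write_sample_info <- function(info, path) write_tsv(validate_sample_info(info), path)

# ---- taxon annotation -----------------------------------------------------

#' Validate a taxon annotation table
#'
#' Required columns: `taxon_id`, `species_name`, `kingdom`
#' (`virus`/`bacterium`), `lifestyle` (`virulent`/`temperate`/`unknown`),
#' `host_genus`, `host_phylum`, `host_link_method`
#' (`nomenclature`/`crassphage_override`/`provided`/`none`). `unknown`
#' lifestyle is permitted only for viral entries (such entries are excluded
#' from LLI computations); bacterial rows may leave lifestyle empty; host
#' fields are populated iff the link method is not `none`.
#'
#' @param ann data.frame of per-taxon annotation.
#' @return the validated data.frame.
#' @export
validate_taxon_annotation <- function(ann) {
  req <- c("taxon_id", "species_name", "kingdom", "lifestyle",
           "host_genus", "host_phylum", "host_link_method")
  missing <- setdiff(req, names(ann))
  if (length(missing))
    pd_stop(paste("annotation missing column(s):", paste(missing, collapse = ", ")),
            "schema_error")
  if (anyDuplicated(ann$taxon_id))
    pd_stop("duplicate taxon_id in annotation", "schema_error")
  if (!all(ann$kingdom %in% c("virus", "bacterium")))
    pd_stop("kingdom must be virus or bacterium", "schema_error")
  ls_empty <- is.na(ann$lifestyle) | ann$lifestyle == ""
  if (!all(ann$lifestyle[!ls_empty] %in% c("virulent", "temperate", "unknown")))
    pd_stop("lifestyle must be virulent, temperate or unknown", "schema_error")
  if (any(ann$kingdom == "virus" & ls_empty))
    pd_stop("viral taxa must carry a lifestyle label", "schema_error")
  if (any(!ls_empty & ann$lifestyle == "unknown" & ann$kingdom != "virus"))
    pd_stop("lifestyle 'unknown' is only permitted for viral taxa", "schema_error")
  if (!all(ann$host_link_method %in%
           c("nomenclature", "crassphage_override", "provided", "none")))
    pd_stop("unknown host_link_method", "schema_error")
  host_empty <- is.na(ann$host_genus) | ann$host_genus == ""
  if (any(ann$host_link_method != "none" & host_empty))
    pd_stop("host_genus must be populated when host_link_method != none",
            "schema_error")
  if (any(ann$host_link_method == "none" & !host_empty))
    pd_stop("host fields must be empty when host_link_method = none",
            "schema_error")
  ann
}

#' Read a taxon annotation table
#' @param path tab-separated annotation file.
#' @export
read_taxon_annotation <- function(path) {
  validate_taxon_annotation(read_tsv(path,
    c("taxon_id", "species_name", "kingdom", "lifestyle",
      "host_genus", "host_phylum", "host_link_method"), "annotation"))
}

#' Write a taxon annotation table
#' @param ann validated annotation.
#' @param path file path.
#' @export
write_taxon_annotation <- function(ann, path) write_tsv(validate_taxon_annotation(ann), path)

# ---- HGT events -----------------------------------------------------------

hgt_cols <- function() {
  c("event_id", "donor_taxon", "recipient_taxon", "donor_genus",
    "recipient_genus", "gene_id", "amino_acid_identity",
    "gene_cluster_coverage", "alignment_length_bp", "group",
    "phage_contig_id", "phage_identity", "phage_evalue", "phage_mediated")
}

#' Validate an HGT event table
#'
#' One row per detected horizontal-gene-transfer event between bacterial
#' genomes, with alignment evidence and an optional phage hit. A
#' `phage_mediated = TRUE` flag requires a recorded phage hit passing the
#' phage screen (identity > 90, E-value < 1e-5).
#'
#' @param events data.frame with columns `event_id`, `donor_taxon`,
#'   `recipient_taxon`, `donor_genus`, `recipient_genus`, `gene_id`,
#'   `amino_acid_identity`, `gene_cluster_coverage`, `alignment_length_bp`,
#'   `group`, `phage_contig_id`, `phage_identity`, `phage_evalue`,
#'   `phage_mediated`.
#' @return the validated data.frame.
#' @export
validate_hgt_events <- function(events) {
  missing <- setdiff(hgt_cols(), names(events))
  if (length(missing))
    pd_stop(paste("HGT table missing column(s):", paste(missing, collapse = ", ")),
            "schema_error")
  if (anyDuplicated(events$event_id))
    pd_stop("duplicate event_id in HGT table", "schema_error")
  events$phage_mediated <- as.logical(events$phage_mediated)
  flagged <- which(events$phage_mediated)
  if (length(flagged)) {
    ok <- !is.na(events$phage_identity[flagged]) &
      !is.na(events$phage_evalue[flagged]) &
      events$phage_identity[flagged] > 90 &
      events$phage_evalue[flagged] < 1e-5
    if (!all(ok))
      pd_stop("phage_mediated = TRUE requires a phage hit passing identity > 90 and E-value < 1e-5",
              "schema_error")
  }
  events
}

#' Read an HGT event table
#' @param path tab-separated file with [validate_hgt_events()] columns.
#' @export
read_hgt_events <- function(path) validate_hgt_events(read_tsv(path, hgt_cols(), "HGT table"))

#' Write an HGT event table
#' @param events validated HGT events.
#' @param path file path.
#' @export
write_hgt_events <- function(events, path) write_tsv(validate_hgt_events(events), path)

# ---- alignment hits (12-column tabular convention) ------------------------

alignment_cols <- function() {
  c("query_id", "subject_id", "identity", "alignment_length", "mismatches",
    "gap_opens", "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score")
}

#' Read alignment hits in the standard 12-column tabular format
#'
#' The headerless tab-separated convention of sequence aligners
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, E-value, bit score).
#' Scientific-notation E-values are parsed as numerics.
#'
#' @param path file path.
#' @return data.frame with columns [alignment_cols()][read_alignment_hits].
#' @export
read_alignment_hits <- function(path) {
  if (!file.exists(path)) pd_stop(sprintf("file not found: %s", path), "io_error")
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) && any(nf != 12L))
    pd_stop(sprintf("alignment rows must have 12 tab-separated columns (saw %s)",
                    paste(unique(nf), collapse = ",")), "parse_error")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = alignment_cols())
  num <- alignment_cols()[3:12]
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && nrow(df)) pd_stop(sprintf("non-numeric %s in %s", cl, path),
                                      "parse_error")
    df[[cl]] <- v
  }
  validate_alignment_hits(df)
}

#' Validate alignment hits
#' @param hits data.frame in the 12-column layout.
#' @export
validate_alignment_hits <- function(hits) {
  missing <- setdiff(alignment_cols(), names(hits))
  if (length(missing))
    pd_stop(paste("alignment hits missing column(s):",
                  paste(missing, collapse = ", ")), "schema_error")
  if (any(hits$identity < 0 | hits$identity > 100))
    pd_stop("identity must lie in [0, 100]", "schema_error")
  if (any(hits$e_value < 0))
    pd_stop("e_value must be nonnegative", "schema_error")
  hits
}

#' Write alignment hits in the headerless 12-column tabular format
#' @param hits validated alignment hits.
#' @param path file path.
#' @export
write_alignment_hits <- function(hits, path) {
  hits <- validate_alignment_hits(hits)
  utils::write.table(hits[alignment_cols()], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- gene-level abundance -------------------------------------------------

#' Validate a gene-level abundance table
#'
#' Long format keyed by gene class (`integrase`, `recombinase`,
#' `transposase`) or KO identifier (e.g. `K14157`), with an optional
#' pathway label and one nonnegative normalized value per sample.
#'
#' @param tab data.frame with columns `gene_key`, `pathway`, `sample_id`,
#'   `value`.
#' @return the validated data.frame.
#' @export
validate_gene_abundance <- function(tab) {
  req <- c("gene_key", "pathway", "sample_id", "value")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    pd_stop(paste("gene table missing column(s):", paste(missing, collapse = ", ")),
            "schema_error")
  if (any(is.na(tab$gene_key) | tab$gene_key == ""))
    pd_stop("gene_key must be nonempty", "schema_error")
  if (any(!is.finite(tab$value) | tab$value < 0))
    pd_stop("gene abundance values must be finite and nonnegative", "schema_error")
  tab
}

#' Read a gene-level abundance table
#' @param path tab-separated file with [validate_gene_abundance()] columns.
#' @export
read_gene_abundance <- function(path) {
  validate_gene_abundance(read_tsv(path,
    c("gene_key", "pathway", "sample_id", "value"), "gene table"))
}

#' Write a gene-level abundance table
#' @param tab validated gene table.
#' @param path file path.
#' @export
write_gene_abundance <- function(tab, path) write_tsv(validate_gene_abundance(tab), path)
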