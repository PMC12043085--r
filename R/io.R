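#' Table dialects understood by the pipeline
#'
#' Every input table is plain UTF-8 TSV with a header row and `.` for missing
#' values. Genomic intervals (`cn_segments`, `gene_coords`, blacklist BEDs)
#' are 0-based half-open, BED style. Clonotype tables additionally accept the
#' ImmunoSEQ column vocabulary (see [immunoseq_rename_map()]).
#'
#' @format A named list: for each dialect, the character vector of required
#'   columns. Extra columns are always preserved, never dropped.
#' @export
table_dialects <- function() {
  list(
    germline_variants = c("patient_id", "gene", "hgvs", "consequence",
                          "population_af", "acmg", "zygosity", "vaf",
                          "depth", "alt_reads", "in_repetitive_region",
                          "matches_somatic_call"),
    iei_panel = c("gene", "iuis_category", "inheritance", "onset",
                  "dysregulation_vs_deficiency"),
    somatic_variants = c("patient_id", "gene", "consequence",
                         "pathogenicity", "vaf"),
    cn_segments = c("patient_id", "chrom", "start", "end", "log2"),
    gene_coords = c("gene", "chrom", "start", "end"),
    repertoire = c("sample_id", "cdr3_aa", "templates", "in_frame",
                   "has_stop"),
    specificity_reference = c("cdr3_aa", "condition_category",
                              "condition_label"),
    expression = "cell_id",
    cell_annotation = c("cell_id", "clone_id", "clone_templates", "group"),
    clinical = "patient_id"
  )
}

#' ImmunoSEQ-style column renames accepted for clonotype tables
#'
#' Maps the vendor export vocabulary onto the canonical repertoire columns.
#' A `frame_type` column with values `In`/`Out`/`Stop` is expanded into the
#' logical `in_frame` / `has_stop` pair.
#'
#' @return Named character vector, `old_name = canonical_name`.
#' @export
immunoseq_rename_map <- function() {
  c(amino_acid = "cdr3_aa", aminoAcid = "cdr3_aa",
    count = "templates", templates = "templates",
    v_gene = "v_gene", vGeneName = "v_gene",
    j_gene = "j_gene", jGeneName = "j_gene",
    sample_name = "sample_id")
}

logical_cols <- c("in_repetitive_region", "matches_somatic_call",
                  "in_frame", "has_stop")
integer_cols <- c("depth", "alt_reads", "start", "end", "templates",
                  "clone_templates")
numeric_cols <- c("population_af", "vaf", "log2", "baf")

as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a validated pipeline table
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect One of the names of [table_dialects()].
#' @return A `data.frame`, row order preserved, required columns validated
#'   and coerced, extra columns kept as read.
#' @details Validation failures are reported precisely: a missing required
#'   column raises a schema error naming the column; a value outside its
#'   domain (e.g. a segment with `start >= end`, a VAF outside `[0,1]`)
#'   raises a row-level error naming the offending line of the file.
#' @export
read_table <- function(path, dialect) {
  dialects <- table_dialects()
  if (!dialect %in% names(dialects)) {
    stop("unknown dialect '", dialect, "'", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df <- canonicalize_table(df, dialect)
  validate_table(df, dialect, source = path)
}

# Apply renames / derived columns so in-memory tables and files share a schema.
canonicalize_table <- function(df, dialect) {
  if (dialect == "repertoire") {
    map <- immunoseq_rename_map()
    hits <- intersect(names(df), names(map))
    for (h in hits) {
      if (!map[[h]] %in% names(df)) names(df)[names(df) == h] <- map[[h]]
    }
    if ("frame_type" %in% names(df) &&
        !all(c("in_frame", "has_stop") %in% names(df))) {
      df$in_frame <- df$frame_type == "In"
      df$has_stop <- df$frame_type == "Stop"
    }
  }
  df
}

#' Validate an in-memory table against a dialect contract
#'
#' @param df A data.frame.
#' @param dialect Dialect name, see [table_dialects()].
#' @param source Label used in error messages (defaults to "table").
#' @return The validated, type-coerced data.frame (invisibly the same rows).
#' @export
validate_table <- function(df, dialect, source = "table") {
  required <- table_dialects()[[dialect]]
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error in ", source, " (dialect '", dialect,
         "'): missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(names(df), logical_cols)) {
    df[[col]] <- as_logical_col(df[[col]])
  }
  for (col in intersect(names(df), integer_cols)) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("row-level error in ", source, " line ", bad[1] + 1L,
           ": unparseable integer in column '", col, "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in intersect(names(df), numeric_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("row-level error in ", source, " line ", bad[1] + 1L,
           ": unparseable number in column '", col, "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  check_domain <- function(cond, what) {
    bad <- which(!is.na(cond) & !cond)
    if (length(bad)) {
      stop("row-level error in ", source, " line ", bad[1] + 1L, ": ", what,
           call. = FALSE)
    }
  }
  if (all(c("start", "end") %in% names(df))) {
    check_domain(df$start < df$end, "interval start must be < end (0-based half-open)")
    check_domain(df$start >= 0L, "interval start must be >= 0")
  }
  if ("vaf" %in% names(df)) {
    check_domain(df$vaf >= 0 & df$vaf <= 1, "vaf must lie in [0, 1]")
  }
  if ("population_af" %in% names(df)) {
    check_domain(df$population_af >= 0 & df$population_af <= 1,
                 "population_af must lie in [0, 1]")
  }
  if (all(c("alt_reads", "depth") %in% names(df))) {
    check_domain(df$alt_reads <= df$depth, "alt_reads must be <= depth")
  }
  if ("templates" %in% names(df)) {
    check_domain(df$templates >= 1L, "templates must be >= 1")
  }
  df
}

#' Write a pipeline table as canonical TSV
#'
#' Tab-separated, UTF-8, `.` for missing, no quoting, no row names —
#' the format [read_table()] reads back.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and re-read a cohort summary
#'
#' The summary is a data.frame with columns `statistic`, `numerator`,
#' `denominator`, `value`, `percent`, `p_value`; columns are emitted in that
#' deterministic order. Re-reading reproduces integers bit-exactly and reals
#' to better than 1e-12.
#'
#' @param summary A cohort summary data.frame (see [summarize_pipeline()]).
#' @param path Output path.
#' @export
write_report <- function(summary, path) {
  cols <- c("statistic", "numerator", "denominator", "value", "percent",
            "p_value")
  for (c0 in setdiff(cols, names(summary))) summary[[c0]] <- NA
  write_table(summary[, cols, drop = FALSE], path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE)
  for (col in c("numerator", "denominator")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Read an expression matrix (dense TSV or MatrixMarket triplet)
#'
#' Dense input: a TSV whose first column is `cell_id` and remaining columns
#' are genes. Sparse input: a MatrixMarket `.mtx` file (genes x cells or
#' cells x genes as stored) with companion row-name and column-name files,
#' one name per line; the result is oriented cells x genes.
#'
#' @param path Path to the dense TSV or `.mtx` file.
#' @param row_names,col_names For MTX input, paths to the row/column name
#'   files.
#' @param rows For MTX input, whether stored rows are `"cells"` or `"genes"`.
#' @return A numeric matrix, cells in rows, genes in columns.
#' @export
read_expression <- function(path, row_names = NULL, col_names = NULL,
                            rows = c("cells", "genes")) {
  rows <- match.arg(rows)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
      stop("MTX dimensions do not match name files", call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
    if (rows == "genes") m <- t(m)
    return(m)
  }
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "cell_id") {
    stop("schema error in ", path,
         " (dialect 'expression'): missing required column(s): cell_id",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  m
}

#' Read a BED interval file (0-based half-open)
#'
#' @param path Path to a headerless 3+ column BED file.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs >= 3 columns: ", path, call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) {
    stop("row-level error in ", path, ": interval start must be < end",
         call. = FALSE)
  }
  df[, 1:3]
}
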