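#' Compute a beta value from methylated/unmethylated intensities
#'
#' beta = Meth / (Meth + Unmeth + offset). The offset guards against
#' division by small total intensities; the conventional default is 100.
#' With a positive offset the result lies in \[0, 1) and equals 0 exactly
#' when the methylated signal is 0.
#'
#' @param meth non-negative methylated probe signal (vectorized).
#' @param unmeth non-negative unmethylated probe signal.
#' @param offset non-negative stabilizing constant added to the denominator.
#' @return numeric vector of beta values.
#' @export
#' @examples
#' compute_beta(900, 0)        # 0.9
#' compute_beta(100, 0)        # 0.5
compute_beta <- function(meth, unmeth, offset = 100) {
  if (length(offset) != 1 || !is.finite(offset) || offset < 0)
    stop("offset must be a single non-negative number", call. = FALSE)
  meth <- as.numeric(meth); unmeth <- as.numeric(unmeth)
  if (length(meth) != length(unmeth))
    stop("meth and unmeth must have equal length", call. = FALSE)
  bad <- !is.na(meth) & !is.na(unmeth) & (meth < 0 | unmeth < 0)
  if (any(bad))
    stop("negative intensities are invalid", call. = FALSE)
  denom <- meth + unmeth + offset
  if (any(denom == 0, na.rm = TRUE))
    stop("all-zero denominator: meth + unmeth + offset must be > 0",
         call. = FALSE)
  meth / denom
}

# Delimiter sniffing on the header line: tab wins if present, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a beta-value matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of site IDs.
#' The delimiter (tab or comma) is sniffed from the header line. Empty
#' cells and the literal `NA` become missing values. Out-of-range values
#' are retained (and flagged only by [qc_filter_samples()]), so that the
#' QC report can name them.
#'
#' @param path file to read.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @param dataset_id optional study-dataset label to attach.
#' @param transpose set `TRUE` if the file has samples in rows; the
#'   orientation is never guessed from the data.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sep = NULL, dataset_id = NULL,
                             transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, na.strings = c("NA", ""),
                      colClasses = list(character = 1), data.table = FALSE,
                      showProgress = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) < 1) stop("format error: no columns in ", path, call. = FALSE)
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    line <- which(ids == dup)[2] + 1L  # +1 for the header row
    stop("format error: duplicated site ID '", dup, "' at line ", line,
         call. = FALSE)
  }
  vals_df <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals_df))   # all-NA columns come back logical
    if (is.logical(vals_df[[j]])) vals_df[[j]] <- as.numeric(vals_df[[j]])
  vals <- as.matrix(vals_df)
  if (nrow(vals) > 0 && ncol(vals) > 0 && !is.numeric(vals)) {
    bad_col <- which(!vapply(dt[-1], is.numeric, logical(1)))[1] + 1L
    bad_row <- which(!grepl("^[-+0-9.eE]*$", as.character(dt[[bad_col]])))[1]
    stop("format error: unparsable numeric in column ", bad_col,
         if (!is.na(bad_row)) paste0(", line ", bad_row + 1L), call. = FALSE)
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  beta_matrix(vals, dataset_id = dataset_id)
}

#' Write a beta-value matrix
#'
#' Values are written with enough significant digits (default 8) that
#' `read_beta_matrix(write_beta_matrix(m))` reproduces `m` to well within
#' 1e-9. Missing values are written as `NA`.
#'
#' @param m a [beta_matrix()].
#' @param path destination file.
#' @param sep field separator, tab by default.
#' @param digits significant digits to keep; `NULL` (default) writes full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, sep = "\t", digits = NULL) {
  stopifnot(inherits(m, "beta_matrix"))
  vals <- if (is.null(digits)) m$values else signif(m$values, digits)
  ids <- site_ids(m)
  if (is.null(ids)) ids <- character(0)  # dimnames of a 0-row matrix
  cols <- c(list(ID = ids),
            lapply(seq_len(ncol(vals)), function(j) vals[, j]))
  df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) == ncol(vals) + 1L)
  colnames(df) <- c("ID", sample_ids(m))
  rownames(df) <- NULL
  data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Drop samples with abnormal beta values
#'
#' Quality control operates on samples, never on sites: any sample
#' containing a beta value below 0, above 1, or a missing value is removed
#' in full. Site order is unchanged. The operation is idempotent.
#'
#' @param m a [beta_matrix()].
#' @return a list with `matrix` (the filtered [beta_matrix()]) and `report`,
#'   a data frame of dropped sample IDs with the reason
#'   (`below_zero`, `above_one`, `missing`; a sample failing several checks
#'   lists all, comma-separated).
#' @export
qc_filter_samples <- function(m) {
  stopifnot(inherits(m, "beta_matrix"))
  v <- m$values
  has_neg <- apply(v, 2, function(x) any(x < 0, na.rm = TRUE))
  has_sup <- apply(v, 2, function(x) any(x > 1, na.rm = TRUE))
  has_na  <- apply(v, 2, anyNA)
  drop <- has_neg | has_sup | has_na
  reason <- vapply(seq_along(drop), function(j) {
    paste(c("below_zero", "above_one", "missing")[
      c(has_neg[j], has_sup[j], has_na[j])], collapse = ",")
  }, character(1))
  report <- data.frame(sample_id = sample_ids(m)[drop],
                       reason = reason[drop],
                       stringsAsFactors = FALSE)
  list(matrix = m[, !drop], report = report)
}

# Closed vocabularies for the probe annotation, modeled on the Illumina
# manifest semantics (gene-region class and relation to CpG islands).
REGION_CLASSES <- c("1stExon", "3'UTR", "5'UTR", "Body", "TSS200",
                    "TSS1500", "none")
CGI_CLASSES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                 "OpenSea")

#' Construct and validate a probe annotation table
#'
#' @param site_id,chrom character vectors.
#' @param pos 1-based genomic coordinates (manifest MAPINFO convention).
#' @param gene gene symbol or `NA`.
#' @param region_class one of `r paste(REGION_CLASSES, collapse=", ")`.
#' @param cgi_class one of `r paste(CGI_CLASSES, collapse=", ")`.
#' @param has_snp logical: any SNP in the array probe.
#' @return a `data.frame` with class `probe_annotation`.
#' @export
probe_annotation <- function(site_id, chrom, pos, gene = NA_character_,
                             region_class = "none", cgi_class = "OpenSea",
                             has_snp = FALSE) {
  df <- data.frame(site_id = as.character(site_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   gene = as.character(gene),
                   region_class = as.character(region_class),
                   cgi_class = as.character(cgi_class),
                   has_snp = as.logical(has_snp),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 0, na.rm = TRUE))
    stop("pos must be non-negative", call. = FALSE)
  if (!all(df$region_class %in% REGION_CLASSES))
    stop("region_class outside vocabulary: ",
         paste(setdiff(df$region_class, REGION_CLASSES), collapse = ", "),
         call. = FALSE)
  if (!all(df$cgi_class %in% CGI_CLASSES))
    stop("cgi_class outside vocabulary: ",
         paste(setdiff(df$cgi_class, CGI_CLASSES), collapse = ", "),
         call. = FALSE)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read / write probe annotation (TSV with columns ID, CHR, MAPINFO, GENE,
#' REGION, RELATION_TO_CGI, HAS_SNP)
#' @param path file path.
#' @return `read_probe_annotation`: a validated [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""), showProgress = FALSE)
  need <- c("ID", "CHR", "MAPINFO", "GENE", "REGION", "RELATION_TO_CGI",
            "HAS_SNP")
  if (!all(need %in% colnames(dt)))
    stop("annotation missing columns: ",
         paste(setdiff(need, colnames(dt)), collapse = ", "), call. = FALSE)
  probe_annotation(dt$ID, dt$CHR, dt$MAPINFO, dt$GENE, dt$REGION,
                   dt$RELATION_TO_CGI, as.logical(dt$HAS_SNP))
}

#' @rdname read_probe_annotation
#' @param ann a [probe_annotation()].
#' @export
write_probe_annotation <- function(ann, path) {
  out <- data.frame(ID = ann$site_id, CHR = ann$chrom, MAPINFO = ann$pos,
                    GENE = ann$gene, REGION = ann$region_class,
                    RELATION_TO_CGI = ann$cgi_class, HAS_SNP = ann$has_snp)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' Per-sample metadata: study dataset, tissue, cell type, condition, sex
#' (`F`, `M` or `unknown`) and age in years.
#'
#' @param sample_id unique sample identifiers.
#' @param dataset_id study-dataset labels.
#' @param tissue,cell_type,condition character metadata.
#' @param sex one of `F`, `M`, `unknown`.
#' @param age optional non-negative ages (years).
#' @return a `data.frame` with class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, dataset_id, tissue = NA_character_,
                         cell_type = NA_character_, condition = NA_character_,
                         sex = "unknown", age = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   dataset_id = as.character(dataset_id),
                   tissue = as.character(tissue),
                   cell_type = as.character(cell_type),
                   condition = as.character(condition),
                   sex = as.character(sex),
                   age = as.numeric(age),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in sample sheet", call. = FALSE)
  if (!all(df$sex %in% c("F", "M", "unknown")))
    stop("sex must be one of F, M, unknown", call. = FALSE)
  if (any(df$age < 0, na.rm = TRUE))
    stop("age must be non-negative", call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read / write a sample sheet (TSV with columns SAMPLE_ID, DATASET_ID,
#' TISSUE, CELL_TYPE, CONDITION, SEX, AGE)
#' @param path file path.
#' @return `read_sample_sheet`: a validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""), showProgress = FALSE)
  need <- c("SAMPLE_ID", "DATASET_ID", "TISSUE", "CELL_TYPE", "CONDITION",
            "SEX", "AGE")
  if (!all(need %in% colnames(dt)))
    stop("sample sheet missing columns: ",
         paste(setdiff(need, colnames(dt)), collapse = ", "), call. = FALSE)
  sx <- dt$SEX
  sx[is.na(sx)] <- "unknown"
  sample_sheet(dt$SAMPLE_ID, dt$DATASET_ID, dt$TISSUE, dt$CELL_TYPE,
               dt$CONDITION, sx, dt$AGE)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- data.frame(SAMPLE_ID = sheet$sample_id, DATASET_ID = sheet$dataset_id,
                    TISSUE = sheet$tissue, CELL_TYPE = sheet$cell_type,
                    CONDITION = sheet$condition, SEX = sheet$sex,
                    AGE = sheet$age)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
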