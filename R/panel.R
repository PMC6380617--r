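#' Genotype panel
#'
#' A \code{genotype_panel} holds an n x M allele-dosage matrix together with
#' sample and marker identifiers and per-marker minor-allele frequencies.
#' Dosages may use any real additive coding; biallelic diploids are typically
#' 0/1/2 and fully inbred lines 0/2. Kinship and design centering are
#' covariant under affine recoding of the dosage scale. Missing values are not
#' allowed: filtering/imputation belongs to load time.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#' @param sample_ids character vector of row identifiers (unique).
#' @param marker_ids character vector of column identifiers (unique).
#' @return An object of class \code{genotype_panel} with fields
#'   \code{dosages}, \code{sample_ids}, \code{marker_ids}, \code{maf}.
#' @export
genotype_panel <- function(dosages,
                           sample_ids = rownames(dosages),
                           marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(dosages))
    stop("length of sample_ids must equal the number of rows", call. = FALSE)
  if (length(marker_ids) != ncol(dosages))
    stop("length of marker_ids must equal the number of columns", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(dosages))
    stop("dosage matrix contains missing values", call. = FALSE)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- marker_ids
  structure(
    list(dosages = dosages, sample_ids = sample_ids,
         marker_ids = marker_ids, maf = marker_maf(dosages)),
    class = "genotype_panel")
}

#' Minor-allele frequencies of a dosage matrix
#'
#' Allele frequency per marker is \code{mean(dosage) / max_dosage}, where the
#' maximum dosage (ploidy scale) is inferred as the dosage range of the coding
#' actually observed (2 for 0/1/2 or 0/2 codings). Returned as the minor
#' (folded) frequency.
#'
#' @param dosages numeric dosage matrix.
#' @param max_dosage dosage carried by a homozygote for the counted allele;
#'   default 2.
#' @return numeric vector of length \code{ncol(dosages)} in [0, 0.5].
#' @export
marker_maf <- function(dosages, max_dosage = 2) {
  p <- colMeans(dosages) / max_dosage
  pmin(p, 1 - p)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d markers\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by sample and/or marker index
#'
#' @param x a genotype_panel.
#' @param i sample (row) indices; missing keeps all.
#' @param j marker (column) indices; missing keeps all.
#' @param ... unused.
#' @return a genotype_panel (MAF recomputed on the subset).
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  genotype_panel(x$dosages[i, j, drop = FALSE],
                 x$sample_ids[i], x$marker_ids[j])
}

apply_maf_filter <- function(panel, maf_threshold, verbose = TRUE) {
  keep <- panel$maf >= maf_threshold & panel$maf > 0
  n_mono <- sum(panel$maf == 0)
  n_low <- sum(!keep) - n_mono
  if (verbose && sum(!keep) > 0)
    message(sprintf(
      "dropped %d marker(s): %d monomorphic, %d with MAF < %g",
      sum(!keep), n_mono, n_low, maf_threshold))
  if (!any(keep))
    stop("no markers left after MAF filtering", call. = FALSE)
  panel[, which(keep)]
}

#' Load a genotype dosage matrix
#'
#' Reads one of two plain-text dialects into a \code{genotype_panel}:
#' \describe{
#'   \item{\code{dosage-csv}}{comma-separated; header row of marker ids; first
#'     column sample id; remaining columns numeric dosages.}
#'   \item{\code{plink-raw}}{whitespace-delimited PLINK \code{--recode A}
#'     style: header then columns FID IID PAT MAT SEX PHENOTYPE followed by
#'     one dosage column per marker. Only IID and the marker columns are used.}
#' }
#' Monomorphic markers are always removed; markers with minor-allele frequency
#' below \code{maf_threshold} are removed and the count reported.
#'
#' @param path file path.
#' @param format \code{"dosage-csv"} or \code{"plink-raw"}.
#' @param maf_threshold MAF filter in [0, 0.5); default 0.05.
#' @return a \code{genotype_panel}.
#' @export
read_dosage <- function(path, format = c("dosage-csv", "plink-raw"),
                        maf_threshold = 0.05) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown genotype format: ",
                                              format[1], call. = FALSE))
  stopifnot(maf_threshold >= 0, maf_threshold < 0.5)
  if (format == "dosage-csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("dosage-csv needs a sample-id column plus markers",
                           call. = FALSE)
    ids <- as.character(df[[1]])
    mat <- df[, -1, drop = FALSE]
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(fixed %in% names(df)[1:6]))
      stop("plink-raw header must start with FID IID PAT MAT SEX PHENOTYPE",
           call. = FALSE)
    ids <- as.character(df[["IID"]])
    mat <- df[, setdiff(names(df), fixed), drop = FALSE]
  }
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric dosage at row %d, column '%s'",
                     bad[1], names(mat)[j]), call. = FALSE)
      mat[[j]] <- vn
    }
  }
  m <- as.matrix(mat)
  if (anyNA(m))
    stop("missing dosage values are not supported; impute or filter first",
         call. = FALSE)
  panel <- genotype_panel(m, sample_ids = ids, marker_ids = colnames(mat))
  apply_maf_filter(panel, maf_threshold)
}

#' Write a genotype panel as dosage-csv
#'
#' @param panel a genotype_panel.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dosage <- function(panel, path) {
  df <- data.frame(sample_id = panel$sample_ids,
                   panel$dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table and align it to a panel
#'
#' The file must be a two-column CSV (sample_id, value) with a header.
#' Values are returned in panel sample order; ids in the file that do not
#' match the panel, or panel samples without a phenotype, raise an error
#' listing the offenders.
#'
#' @param path CSV file path.
#' @param panel a genotype_panel to align against.
#' @return named numeric vector over \code{panel$sample_ids}.
#' @export
read_phenotype <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype CSV needs (sample_id, value) columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.numeric(df[[2]])
  extra <- setdiff(ids, panel$sample_ids)
  if (length(extra))
    stop("phenotype ids not in panel: ", paste(extra, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(panel$sample_ids, ids)
  if (length(miss))
    stop("panel samples without phenotype: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- vals[match(panel$sample_ids, ids)]
  names(out) <- panel$sample_ids
  out
}

#' Standardize a phenotype to unit variance
#'
#' Rescales (without recentering) so that the sample variance equals one, the
#' convention required before EthAcc-criterion training-set optimization: the
#' predicted-genetic-value variance constraint compares against a phenotypic
#' variance of 1.
#'
#' @param y numeric phenotype vector.
#' @return rescaled vector with attribute \code{standardized = TRUE}.
#' @export
standardize_phenotype <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant phenotype", call. = FALSE)
  out <- y / s
  attr(out, "standardized") <- TRUE
  out
}
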