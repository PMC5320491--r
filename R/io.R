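#' Read and write omics matrices as tab-separated text
#'
#' Matrices are stored as TSV with a one-line header: the first column holds
#' feature ids, the remaining columns one subject each. Values are written
#' with 15 significant digits, so a write/read round trip preserves ids
#' exactly and values to better than 12 significant digits. Reading validates
#' the file strictly: ragged rows, duplicated feature ids, duplicated subject
#' ids and non-numeric cells are parse errors that name the offending line.
#'
#' @param path file path.
#' @param modality modality tag attached on read (`"expression_log2"` or
#'   `"methylation_beta"`).
#' @return `read_omics_matrix`: an `omics_matrix`; `write_omics_matrix`:
#'   `path`, invisibly.
#' @export
read_omics_matrix <- function(path, modality = c("expression_log2",
                                                 "methylation_beta")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2)
    stopf("parse error in %s: need a header line and at least one feature row",
          path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_exp <- length(header)
  if (ncol_exp < 2) stopf("parse error in %s, line 1: no subject columns", path)
  subjects <- header[-1]
  if (anyDuplicated(subjects))
    stopf("parse error in %s, line 1: duplicated subject id '%s'",
          path, subjects[duplicated(subjects)][1])
  body <- fields[-1]
  lens <- lengths(body)
  if (any(lens != ncol_exp))
    stopf("parse error in %s, line %d: expected %d fields, found %d",
          path, which(lens != ncol_exp)[1] + 1, ncol_exp,
          lens[which(lens != ncol_exp)[1]])
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stopf("parse error in %s, line %d: duplicated feature id '%s'",
          path, which(duplicated(ids))[1] + 1, ids[duplicated(ids)][1])
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_exp - 1,
                 dimnames = list(ids, subjects))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v))
      stopf("parse error in %s, line %d: non-numeric cell '%s'",
            path, i + 1, body[[i]][-1][which(is.na(v))[1]])
    vals[i, ] <- v
  }
  structure(list(modality = modality, values = vals), class = "omics_matrix")
}

#' @param x an `omics_matrix`.
#' @rdname read_omics_matrix
#' @export
write_omics_matrix <- function(x, path) {
  if (!inherits(x, "omics_matrix")) stopf("x must be an omics_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  rows <- apply(x$values, 1, function(r)
    paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(x$values), rows, sep = "\t"), con)
  invisible(path)
}

#' Read and write phenotype tables as tab-separated text
#'
#' @param path file path.
#' @return `read_phenotypes`: a validated phenotype table;
#'   `write_phenotypes`: `path`, invisibly.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ph <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_phenotypes(ph)
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' @param ph a phenotype table.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(ph, path) {
  validate_phenotypes(ph)
  utils::write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result table as tab-separated text
#'
#' Generic TSV writer for association lists, sex-specific calls and overlap
#' summaries.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
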