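## Readers and writers for the delimited-text study formats.

#' @importFrom utils read.table write.table count.fields
NULL

## detect comma vs tab on the first line
.detectSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

## read one square headerless connectivity matrix
.readMatrixFile <- function(path, subjectId) {
  M <- as.matrix(read.table(path, sep = .detectSep(path), header = FALSE))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  validateConnectivityMatrix(M, subjectId)
  M
}

#' Read a study from delimited text
#'
#' Matrices come either as one square, headerless, comma- or tab-delimited
#' file per subject (file base names are the subject ids) or as a single
#' long-format table with header columns `subject_id`, `s`, `t`, `value`
#' (1-based region indices, upper triangle).  The covariate table is a
#' delimited file with a header containing `subject_id`, the binary label
#' `A`, and any baseline covariates.  Every matrix is validated; failures
#' name the subject and entry.
#'
#' @param matrixSource directory, vector of matrix file paths, or a single
#'   long-format file.
#' @param covariateTable path to the covariate table.
#' @param regionLabels optional character vector of region names.
#' @return a [ConnectivityStudy-class].
#' @export
readStudy <- function(matrixSource, covariateTable, regionLabels = NULL) {
  if (!file.exists(covariateTable))
    stop("covariate table not found: ", covariateTable)
  covar <- read.table(covariateTable, sep = .detectSep(covariateTable),
                      header = TRUE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% colnames(covar))
    stop("covariate table must contain a subject_id column")
  if (length(matrixSource) == 1L && dir.exists(matrixSource))
    matrixSource <- list.files(matrixSource, full.names = TRUE)
  isLong <- length(matrixSource) == 1L && !dir.exists(matrixSource) &&
    grepl("subject_id", readLines(matrixSource, n = 1L), fixed = TRUE)
  if (isLong) {
    ## long format
    long <- read.table(matrixSource, sep = .detectSep(matrixSource),
                       header = TRUE, stringsAsFactors = FALSE)
    need <- c("subject_id", "s", "t", "value")
    if (!all(need %in% colnames(long)))
      stop("long-format table needs columns: ", paste(need, collapse = ", "))
    p <- max(long$t)
    mats <- lapply(split(long, long$subject_id), function(df) {
      M <- diag(p)
      M[cbind(df$s, df$t)] <- df$value
      M[cbind(df$t, df$s)] <- df$value
      M
    })
    mats <- mats[unique(long$subject_id)]
  } else {
    ids <- sub("\\.(csv|tsv|txt)$", "", basename(matrixSource))
    mats <- Map(.readMatrixFile, matrixSource, ids)
    names(mats) <- ids
  }
  ConnectivityStudy(mats, covar, regionLabels = regionLabels)
}

#' Write a study as delimited text
#'
#' One comma-delimited square matrix file per subject plus a covariate
#' table, the same formats [readStudy()] accepts.
#'
#' @param study a [ConnectivityStudy-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeStudy <- function(study, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(ncol(study))) {
    M <- connectivityMatrix(study, i)
    write.table(format(M, digits = 17L),
                file.path(dir, "matrices", paste0(colnames(study)[i], ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  cd <- as.data.frame(colData(study))
  cd <- cbind(subject_id = colnames(study), cd)
  write.table(cd, file.path(dir, "covariates.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Serialize a density estimate to structured text
#'
#' @param d a [DensityEstimate-class].
#' @param path output file (JSON).
#' @return invisibly, the path.
#' @export
writeDensityEstimate <- function(d, path) {
  rec <- list(method = d@method, support = d@support, n = d@n,
              knots = d@knots, coefficients = d@coefficients,
              lambda = d@lambda, logNormConst = d@logNormConst,
              bandwidth = d@bandwidth, sample = d@sample)
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a serialized density estimate
#'
#' @param path file written by [writeDensityEstimate()].
#' @return a [DensityEstimate-class].
#' @export
readDensityEstimate <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DensityEstimate", support = rec$support, method = rec$method,
      knots = as.numeric(rec$knots),
      coefficients = as.numeric(rec$coefficients),
      lambda = as.numeric(rec$lambda),
      logNormConst = as.numeric(rec$logNormConst),
      bandwidth = as.numeric(rec$bandwidth),
      sample = as.numeric(rec$sample), n = as.integer(rec$n))
}

#' Write a function sample as a two-column table
#'
#' @param fs a [FunctionSample-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFunctionSample <- function(fs, path) {
  write.table(data.frame(grid = fs@grid, value = fs@values), path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a region-by-region matrix with labels
#'
#' @param M square matrix.
#' @param path output file.
#' @param labels optional region labels (default R1..Rp).
#' @return invisibly, the path.
#' @export
writeRegionMatrix <- function(M, path, labels = NULL) {
  p <- nrow(M)
  if (is.null(labels)) labels <- sprintf("R%d", seq_len(p))
  dimnames(M) <- list(labels, labels)
  write.table(cbind(region = labels, format(M, digits = 10L)), path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
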