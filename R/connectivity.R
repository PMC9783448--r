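#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

## ---------------------------------------------------------------------------
## ConnectivityMatrix validation and vectorization
## ---------------------------------------------------------------------------

#' Validate a subject connectivity matrix
#'
#' A valid connectivity matrix is square with p >= 3 regions, symmetric to
#' 1e-10, has unit diagonal, off-diagonal entries in [-1, 1], and no missing
#' values.  Violations are reported with the offending entry named.
#'
#' @param C numeric square matrix of region-by-region correlations.
#' @param subjectId identifier used in error messages.
#' @return `C`, invisibly, when valid; otherwise an error is thrown.
#' @export
validateConnectivityMatrix <- function(C, subjectId = "subject") {
  if (!is.matrix(C) || !is.numeric(C) || nrow(C) != ncol(C))
    stop(sprintf("%s: connectivity must be a square numeric matrix", subjectId))
  p <- nrow(C)
  if (p < 3L)
    stop(sprintf("%s: need at least 3 regions, got %d", subjectId, p))
  bad <- which(!is.finite(C), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: missing or non-finite entry at (%d, %d)",
                 subjectId, bad[1L, 1L], bad[1L, 2L]))
  asym <- abs(C - t(C))
  if (max(asym) > 1e-10) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: matrix not symmetric at (%d, %d): |C[s,t] - C[t,s]| = %.3g",
                 subjectId, ij[1L], ij[2L], max(asym)))
  }
  if (any(abs(diag(C) - 1) > 1e-10))
    stop(sprintf("%s: diagonal entry %d is %.6f, expected 1",
                 subjectId, which(abs(diag(C) - 1) > 1e-10)[1L],
                 diag(C)[which(abs(diag(C) - 1) > 1e-10)[1L]]))
  off <- C; diag(off) <- 0
  if (any(abs(off) > 1 + 1e-12)) {
    ij <- which(abs(off) > 1 + 1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: correlation out of [-1, 1] at (%d, %d): %.6f",
                 subjectId, ij[1L], ij[2L], C[ij[1L], ij[2L]]))
  }
  invisible(C)
}

#' Row-major upper-triangle edge indices
#'
#' @param p number of regions.
#' @return data.frame with columns `s`, `t` (1-based, s < t), in row-major
#'   order: (1,2), (1,3), ..., (1,p), (2,3), ...
#' @export
edgeIndex <- function(p) {
  s <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  t <- sequence((p - 1L):1L) + s
  data.frame(s = as.integer(s), t = as.integer(t))
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the p(p-1)/2 off-diagonal correlations in canonical row-major
#' (s < t) order.  The diagonal is excluded.  The matrix is validated first.
#'
#' @param C a connectivity matrix (see [validateConnectivityMatrix()]).
#' @param subjectId identifier carried on the result.
#' @return an [EdgeSample-class].
#' @examples
#' C <- diag(3); C[1,2] <- C[2,1] <- 0.2; C[1,3] <- C[3,1] <- -0.1
#' C[2,3] <- C[3,2] <- 0.5
#' vectorizeUpperTriangle(C)@values   # 0.2 -0.1 0.5
#' @export
vectorizeUpperTriangle <- function(C, subjectId = "subject") {
  validateConnectivityMatrix(C, subjectId)
  p <- nrow(C)
  idx <- edgeIndex(p)
  new("EdgeSample", subjectId = as.character(subjectId),
      values = C[cbind(idx$s, idx$t)], s = idx$s, t = idx$t)
}

## Inverse of vectorizeUpperTriangle: rebuild the symmetric matrix.
.edgesToMatrix <- function(values, p) {
  C <- diag(p)
  idx <- edgeIndex(p)
  C[cbind(idx$s, idx$t)] <- values
  C[cbind(idx$t, idx$s)] <- values
  C
}

#' Relabel the regions of a connectivity matrix
#'
#' Applies a permutation of the region labels: entry (i, j) of the result is
#' entry (perm[i], perm[j]) of the input.
#'
#' @param C connectivity matrix.
#' @param perm integer permutation of `seq_len(nrow(C))`.
#' @return the relabeled matrix.
#' @export
relabelRegions <- function(C, perm) {
  p <- nrow(C)
  if (length(perm) != p || !setequal(perm, seq_len(p)))
    stop("perm must be a permutation of 1..p")
  C[perm, perm]
}

## ---------------------------------------------------------------------------
## ConnectivityStudy: the study-level container
## ---------------------------------------------------------------------------

#' ConnectivityStudy: a study of connectivity matrices with covariates
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the vectorized upper triangles of all subjects' connectivity
#' matrices in the `"edges"` assay (edges x subjects), the edge region-pair
#' indices in `rowData`, and the subject covariate table (binary treatment
#' label `A`, baseline design columns) in `colData`.  The number of regions
#' is kept in `metadata(x)$nRegions`.
#'
#' @exportClass ConnectivityStudy
setClass("ConnectivityStudy", contains = "SummarizedExperiment")

setValidity("ConnectivityStudy", function(object) {
  if (!"edges" %in% SummarizedExperiment::assayNames(object))
    return("missing 'edges' assay")
  p <- S4Vectors::metadata(object)$nRegions
  if (is.null(p)) return("metadata must record nRegions")
  if (nrow(object) != p * (p - 1) / 2)
    return("edge count inconsistent with nRegions")
  cd <- colData(object)
  if (!"A" %in% colnames(cd)) return("colData must contain treatment label A")
  if (!all(cd$A %in% c(0L, 1L))) return("A must be binary 0/1")
  if (anyDuplicated(colnames(object))) return("duplicate subject ids")
  labs <- S4Vectors::metadata(object)$regionLabels
  if (!is.null(labs) && length(labs) != p)
    return("regionLabels must have length nRegions")
  TRUE
})

#' Build a ConnectivityStudy from matrices and a covariate table
#'
#' @param matrices named list of connectivity matrices (one per subject, all
#'   the same dimension); names are the subject ids.
#' @param covariates data.frame with one row per subject, a binary column
#'   `A`, and optionally a `subject_id` column used to match matrices;
#'   remaining numeric columns become baseline covariates.  An intercept
#'   column is added in [designMatrix()] if not present.
#' @param regionLabels optional character vector of region names, length p.
#' @return a [ConnectivityStudy-class].
#' @export
ConnectivityStudy <- function(matrices, covariates, regionLabels = NULL) {
  if (length(matrices) == 0L) stop("no connectivity matrices supplied")
  ids <- names(matrices)
  if (is.null(ids)) {
    ids <- if (!is.null(covariates$subject_id))
      as.character(covariates$subject_id) else sprintf("S%03d", seq_along(matrices))
    names(matrices) <- ids
  }
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(covariates$subject_id)) {
    cid <- as.character(covariates$subject_id)
    miss <- setdiff(ids, cid)
    if (length(miss) > 0L)
      stop("subjects missing from the covariate table: ",
           paste(miss, collapse = ", "))
    covariates <- covariates[match(ids, cid), , drop = FALSE]
    covariates$subject_id <- NULL
  } else if (nrow(covariates) != length(matrices)) {
    stop("covariate rows do not match the number of matrices")
  }
  p <- nrow(matrices[[1L]])
  edges <- vapply(ids, function(id) {
    Ci <- matrices[[id]]
    if (nrow(Ci) != p)
      stop(sprintf("%s: dimension %d does not match study dimension %d",
                   id, nrow(Ci), p))
    vectorizeUpperTriangle(Ci, id)@values
  }, numeric(p * (p - 1L) / 2L))
  idx <- edgeIndex(p)
  se <- SummarizedExperiment(
    assays = SimpleList(edges = edges),
    rowData = DataFrame(s = idx$s, t = idx$t),
    colData = DataFrame(covariates, row.names = ids))
  obj <- methods::as(se, "ConnectivityStudy")
  S4Vectors::metadata(obj)$nRegions <- p
  S4Vectors::metadata(obj)$regionLabels <- regionLabels
  validObject(obj)
  obj
}

#' @describeIn ConnectivityStudy number of regions p.
#' @param x a `ConnectivityStudy`.
#' @export
nRegions <- function(x) S4Vectors::metadata(x)$nRegions

#' @describeIn ConnectivityStudy binary treatment labels, one per subject.
#' @export
treatmentLabels <- function(x) as.integer(colData(x)$A)

#' @describeIn ConnectivityStudy reassemble one subject's square matrix.
#' @param subject subject id or column index.
#' @export
connectivityMatrix <- function(x, subject) {
  .edgesToMatrix(assay(x, "edges")[, subject], nRegions(x))
}

#' Baseline design matrix of a study or covariate table
#'
#' Extracts the baseline covariate columns (everything except `A` and
#' bookkeeping columns) as a numeric design matrix whose first column is the
#' intercept, adding the intercept when absent.
#'
#' @param x a [ConnectivityStudy-class] or a data.frame of covariates.
#' @return numeric matrix, n x q, first column all ones, full column rank.
#' @export
designMatrix <- function(x) {
  cd <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x)) else
    as.data.frame(x)
  cd <- cd[, setdiff(colnames(cd), c("A", "subject_id", "stimulatedRegion")),
           drop = FALSE]
  keep <- vapply(cd, is.numeric, logical(1L))
  X <- as.matrix(cd[, keep, drop = FALSE])
  hasIntercept <- ncol(X) > 0L && all(X[, 1L] == 1)
  if (!hasIntercept)
    X <- cbind(intercept = 1, X)
  else colnames(X)[1L] <- "intercept"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("baseline design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

setMethod("show", "ConnectivityStudy", function(object) {
  cat(sprintf("ConnectivityStudy: %d subjects, %d regions (%d edges)\n",
              ncol(object), nRegions(object), nrow(object)))
  a <- treatmentLabels(object)
  cat(sprintf("  treatment A = 1: %d subjects; A = 0: %d subjects\n",
              sum(a == 1L), sum(a == 0L)))
  cat(sprintf("  covariates: %s\n",
              paste(colnames(colData(object)), collapse = ", ")))
})
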