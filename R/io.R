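# Readers and writers for the matrix formats the tool touches: Matrix
# Market coordinate files for sparse data, delimited text (CSV/TSV) for
# dense data and factor matrices.

.looksNumeric <- function(fields) {
    suppressWarnings(!anyNA(as.numeric(fields)))
}

#' Read a non-negative data matrix
#'
#' Matrix Market coordinate files (1-based indices; duplicate entries are
#' summed, per the format's convention) are read into sparse storage via
#' \pkg{Matrix}. Delimited files (comma or tab separated, with or without
#' a header line, auto-detected) are read as dense matrices. Negative
#' entries are rejected with the offending position.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension: \code{.mtx} is Matrix
#'   Market, anything else delimited), \code{"mtx"}, or
#'   \code{"delimited"}.
#' @return A dense \code{matrix} or a \code{Matrix::dgCMatrix}.
#' @export
readMatrix <- function(path, format = c("auto", "mtx", "delimited")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
                  else "delimited"
    X <- if (format == "mtx") {
        methods::as(Matrix::readMM(path), "CsparseMatrix")
    } else {
        first <- strsplit(readLines(path, n = 1L), "[,\t]")[[1L]]
        sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
        header <- !.looksNumeric(first)
        as.matrix(read.table(path, sep = sep, header = header))
    }
    .checkNonnegativeInput(X, path)
    X
}

.checkNonnegativeInput <- function(X, path) {
    vals <- if (.isSparse(X)) methods::as(X, "CsparseMatrix")@x else X
    if (anyNA(vals)) stop("non-numeric or missing values in ", path)
    if (any(vals < 0)) {
        idx <- which(as.matrix(X) < 0, arr.ind = TRUE)[1L, ]
        stop("negative entry in ", path, " at row ", idx[1L],
             ", column ", idx[2L])
    }
    invisible(TRUE)
}

#' Write a data matrix
#'
#' Sparse matrices are written as Matrix Market coordinate files
#' (\code{format = "mtx"}), dense matrices as comma-delimited text.
#'
#' @param X dense or sparse non-negative matrix.
#' @param path output path.
#' @param format \code{"auto"} (sparse storage goes to mtx, dense to
#'   delimited), \code{"mtx"}, or \code{"delimited"}.
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(X, path, format = c("auto", "mtx", "delimited")) {
    format <- match.arg(format)
    if (format == "auto") format <- if (.isSparse(X)) "mtx" else "delimited"
    if (format == "mtx") {
        X <- methods::as(methods::as(X, "generalMatrix"), "TsparseMatrix")
        Matrix::writeMM(X, path)
    } else {
        .writeDelimited(as.matrix(X), path)
    }
    invisible(path)
}

# full-precision CSV: 17 significant digits round-trip doubles exactly
.writeDelimited <- function(A, path) {
    txt <- matrix(formatC(A, digits = 17, format = "g"), nrow(A), ncol(A))
    write.table(txt, path, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the three factor matrices to delimited text
#'
#' Writes \code{<prefix>.U.csv}, \code{<prefix>.S.csv} and
#' \code{<prefix>.V.csv} at full precision (17 significant digits), so a
#' round-trip through [readFactors()] reproduces the values exactly. If
#' the target directory does not exist the call fails before any file is
#' written.
#'
#' @param F a [FactorTriple-class].
#' @param prefix path prefix for the three files.
#' @return The three paths, invisibly.
#' @export
writeFactors <- function(F, prefix) {
    dir <- dirname(prefix)
    if (!dir.exists(dir))
        stop("directory does not exist: ", dir, " (no files written)")
    paths <- paste0(prefix, c(".U.csv", ".S.csv", ".V.csv"))
    .writeDelimited(F@U, paths[1L])
    .writeDelimited(F@S, paths[2L])
    .writeDelimited(F@V, paths[3L])
    invisible(paths)
}

#' @describeIn writeFactors Read factors written by \code{writeFactors}.
#' @param prefix path prefix used when writing.
#' @export
readFactors <- function(prefix) {
    rd <- function(p) as.matrix(read.table(p, sep = ",", header = FALSE))
    factorTriple(rd(paste0(prefix, ".U.csv")),
                 rd(paste0(prefix, ".S.csv")),
                 rd(paste0(prefix, ".V.csv")))
}
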