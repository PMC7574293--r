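# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Write a feature-by-sample matrix as TSV
#'
#' Plain-text layout used throughout the package: header row with sample
#' identifiers, feature identifiers in the first column (\code{feature_id}).
#'
#' @param m numeric matrix with row and column names.
#' @param path output file path.
#' @param idColumn name of the identifier column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path, idColumn = "feature_id") {
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                dimnames = dimnames(m))  # full precision: exact round trips
  df <- data.frame(rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path file written by \code{\link{writeMatrixTSV}} (or any TSV with
#'   identifiers in the first column).
#' @return numeric matrix with row names from the first column.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}
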