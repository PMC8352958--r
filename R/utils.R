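#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Coerce a profile or plain matrix to a samples x features matrix
#'
#' Most analysis functions accept either an [abundance_profile] or a bare
#' numeric matrix with sample rows; this normalises the input.
#' @noRd
as_profile_matrix <- function(x) {
  if (inherits(x, "abundance_profile")) return(x$matrix)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x) && is.logical(x)) storage.mode(x) <- "numeric"
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid("expected an abundance_profile or a numeric samples x features matrix")
  }
  x
}

#' Relative-abundance profile container
#'
#' A light S3 container pairing a samples x features relative-abundance matrix
#' with its aggregation level (`"gene"`, `"phylum"`, `"genus"`, `"species"` or
#' `"ko"`) and optional feature metadata. Gene-level rows sum to 1 (up to
#' rounding) unless a sample had no mapped reads; aggregated levels keep the
#' unannotated remainder out, so their row sums are at most 1.
#'
#' @param matrix numeric matrix, samples in rows, features in columns.
#' @param level character scalar naming the aggregation level.
#' @param metadata optional data.frame of per-feature annotation.
#' @return An object of class `abundance_profile`.
#' @export
abundance_profile <- function(matrix, level = "gene", metadata = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_invalid("profile matrix must be a numeric matrix")
  }
  if (any(matrix < 0)) stop_invalid("profile entries must be nonnegative")
  structure(list(matrix = matrix, level = level, metadata = metadata),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> level=%s  %d samples x %d features\n",
              x$level, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.abundance_profile <- function(x) dim(x$matrix)
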