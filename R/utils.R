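#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib lupusnlp, .registration = TRUE
NULL

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so that a seed argument fully determines the result.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

stopifnot_proportion <- function(x, name) {
  if (!is_proportion(x)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
}

#' Class labels used throughout the package
#'
#' Patients are labelled `"SLE"` (case) or `"CONTROL"`. Helper returning the
#' canonical label factor levels, with `"CONTROL"` first so that `"SLE"` is
#' the positive class in all score/AUC computations.
#'
#' @return Character vector `c("CONTROL", "SLE")`.
#' @export
pheno_levels <- function() c("CONTROL", "SLE")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), pheno_levels())
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(labels, levels = pheno_levels())
}
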