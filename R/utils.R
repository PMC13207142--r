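# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so simulation functions are deterministic
#' without clobbering the user's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# The four design groups, in the fixed order used throughout the package.
group_levels <- function() c("PS_male", "PS_female", "Control_male", "Control_female")

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("counts must be finite and non-negative")
  }
  invisible(counts)
}
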