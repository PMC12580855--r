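## Internal helpers shared across modules.

# row/column medians ignoring NA; apply() is fast enough at the matrix sizes
# this package targets (a few thousand proteins, a few hundred samples)
rowMedians2 <- function(x) apply(x, 1L, median, na.rm = TRUE)
colMedians2 <- function(x) apply(x, 2L, median, na.rm = TRUE)

# run an expression under a temporary RNG state seeded by `seed`,
# restoring the caller's RNG afterwards
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# extract the abundance assay from a SummarizedExperiment (or pass a plain
# matrix through), always with dimnames
.abundance <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
  x
}

# extract a traits data.frame from colData or pass a data.frame through
.traits <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(as.data.frame(SummarizedExperiment::colData(x)))
  as.data.frame(x)
}

.checkFraction <- function(x, name, openTop = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      (if (openTop) x >= 1 else x > 1))
    stop(sprintf("'%s' must be a fraction in [0, %s]", name,
                 if (openTop) "1)" else "1]"), call. = FALSE)
  invisible(x)
}
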