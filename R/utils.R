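# internal validation and IO helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    allow_equal_lower = TRUE,
                                    allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

# all simulators take their randomness from one RNG stream seeded per call,
# restoring the caller's RNG state on exit
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] that reports ragged rows with
#' the offending file and line number instead of silently recycling.
#'
#' @param path Path to a TSV file with a header row.
#' @param ... Passed on to [utils::read.delim()].
#' @return A data.frame.
#' @export
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != nfield[1L])
  if (length(bad) > 0L)
    stop(sprintf(
      "ragged TSV: %s line %d has %d fields (header has %d)",
      path, bad[1L], nfield[bad[1L]], nfield[1L]), call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a tab-separated table
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

random_peptide_seqs <- function(n, len_range = c(7L, 20L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1L))
}
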