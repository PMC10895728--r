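# internal helpers

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stage tag; stays < 2^31.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483629)
}

readTSV <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

writeTSV <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalize a micro/milli/gram unit string to one of g, mg, ug.
normalizeUnit <- function(u) {
  u <- trimws(u)
  u[u %in% c("µg", "mcg")] <- "ug"
  bad <- setdiff(unique(u), .VALID_UNITS)
  if (length(bad))
    stop("unknown nutrient unit: ", paste(bad, collapse = ", "), call. = FALSE)
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a
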