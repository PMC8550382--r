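## Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

## Byte-order (C locale) sort, so tie-breaks are identical across platforms.
lexSort <- function(x) sort(x, method = "radix")
lexOrder <- function(...) order(..., method = "radix")

edgeKey <- function(tail, head) paste(tail, head, sep = "\x1f")

## Read a delimited table, separator chosen from the file extension
## (.csv -> comma, anything else -> tab).
readDelimAuto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
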