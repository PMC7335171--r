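# internal helpers

# geometric mean on the log2 scale; all values must be > 0
.geomean <- function(x) 2^mean(log2(x))

.stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# deterministic TSV writer: no quoting, no row names, fixed separator
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
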