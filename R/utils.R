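# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Error signalled for malformed user data (files, queries, configs).
abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("raredx_data_error", "error", "condition")))
}

# Error signalled for bad command-line usage.
abort_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("raredx_usage_error", "error", "condition")))
}

# Byte-stable TSV writer: LF line endings, optional "# key=value" metadata
# header lines, doubles rendered with 15 significant digits.
write_tsv_stable <- function(df, path, meta = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con, sep = "\n")
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.double(x)) trimws(formatC(x, digits = 15, format = "g")) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

# Read a TSV written by write_tsv_stable, skipping "# " metadata lines.
read_tsv_stable <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "# ")
  utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                    sep = "\t", quote = "", stringsAsFactors = FALSE)
}
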