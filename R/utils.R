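# internal helpers: error conditions, seeded RNG scoping, logging

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("screglink_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io <- function(msg, ...) {
  stop(structure(
    class = c("screglink_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parse <- function(msg, ...) {
  stop(structure(
    class = c("screglink_parse_error", "screglink_validation_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("'seed' must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., quiet = getOption("screglink.quiet", FALSE)) {
  if (!isTRUE(quiet)) message(...)
}

# deterministic TSV writer: fixed column order, tab sep, LF endings, no quotes
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
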