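#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors are classed so tests
# can assert on the condition class rather than message text.

fc_abort <- function(msg, class = "famcontext_validation_error", ...) {
  stop(structure(
    class = c(class, "famcontext_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

fc_assert <- function(ok, msg, class = "famcontext_validation_error") {
  if (!isTRUE(ok)) fc_abort(msg, class)
  invisible(TRUE)
}

# scalar checks -------------------------------------------------------------

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_prob <- function(x) is_number(x) && x >= 0 && x <= 1

fc_match_arg <- function(arg, choices) {
  fc_assert(is.character(arg) && length(arg) == 1L && arg %in% choices,
            sprintf("'%s' must be one of: %s",
                    deparse(substitute(arg)), paste(choices, collapse = ", ")),
            class = "famcontext_parameter_error")
  arg
}

# deterministic seeded evaluation without touching the caller's RNG state
with_fc_seed <- function(seed, code) {
  fc_assert(is_count(seed), "'seed' must be a non-negative integer",
            class = "famcontext_parameter_error")
  withr::with_seed(as.integer(seed), code)
}

# stable (locale-independent) string ordering used wherever output order
# must be byte-reproducible
fc_order <- function(...) order(..., method = "radix")

fc_sort <- function(x) sort(x, method = "radix")

# write a data.frame as the package's canonical TSV dialect
write_fc_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_fc_tsv <- function(path, required = character()) {
  fc_assert(file.exists(path), sprintf("file not found: %s", path),
            class = "famcontext_io_error")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    fc_abort(sprintf("%s: missing required column(s): %s",
                     path, paste(missing, collapse = ", ")),
             class = "famcontext_format_error")
  }
  df
}
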