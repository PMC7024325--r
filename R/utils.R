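# Internal condition helpers.  The CLI maps these classes onto exit codes
# (validation/argument -> 2, degenerate input -> 3), so every user-facing
# error raised by the package should go through one of them.

ps_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pharmscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) ps_stop(msg, "ps_validation_error")
stop_argument   <- function(msg) ps_stop(msg, c("ps_argument_error", "ps_validation_error"))
stop_degenerate <- function(msg) ps_stop(msg, "ps_degenerate_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

# Multiplicative string hash over a deparsed object; used only for run
# logs (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Normalise labels given either as a named character vector or as a
# data.frame with compound_id / label columns.  Values must be
# "active"/"inactive".
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("compound_id", "label") %in% names(labels)))
      stop_validation("label data.frame needs 'compound_id' and 'label' columns")
    labels <- stats::setNames(as.character(labels$label), labels$compound_id)
  }
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop_validation("labels must be named by compound_id")
  bad <- setdiff(unique(labels), c("active", "inactive"))
  if (length(bad))
    stop_validation(sprintf("labels must be 'active' or 'inactive' (got: %s)",
                            paste(bad, collapse = ", ")))
  if (anyDuplicated(names(labels)))
    stop_validation("duplicated compound_id in labels")
  labels
}
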