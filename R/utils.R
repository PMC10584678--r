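# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kexdyn <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "kexdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_num <- function(x, name, positive = FALSE, finite = TRUE, len = NULL) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop(sprintf("`%s` must have length %d", name, len), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Deterministic child seed derived from a user seed and a label, kept below
# .Machine$integer.max so it is always a valid R integer seed.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587L + 1)
}
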