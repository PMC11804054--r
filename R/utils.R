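`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sm <- function(fmt, ..., class = "spatialmux_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warn_sm <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage-specific seed from a run seed
#'
#' All randomness in a pipeline run flows from one seed; each stage draws
#' from a seed derived by hashing the stage name, so stages are
#' independently reproducible.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return An integer seed below `2^31`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
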