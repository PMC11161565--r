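#' @importFrom data.table data.table fread fwrite setnames setcolorder as.data.table rbindlist :=
#' @importFrom stats lm coef cor runif rnorm quantile setNames complete.cases
#' @importFrom utils head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log a message to standard error
#'
#' All pipeline logging goes through this helper so that structured output
#' on stdout stays machine-readable.
#'
#' @param ... pasted into the message.
#' @param level one of "INFO", "WARN".
#' @keywords internal
pa_log <- function(..., level = "INFO") {
  message(sprintf("[patrace %s] %s", level, paste0(...)))
}

#' Derive a per-stage child seed from a global seed
#'
#' One global seed fans out to independent per-stage seeds so that stages
#' can be rerun in isolation and still reproduce the full-pipeline run.
#' The rule is a fixed integer hash of the stage name folded into the
#' global seed, reduced modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return a positive integer seed.
#' @export
#' @examples
#' child_seed(42, "simulate")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483563 + 1)
}

# Canonicalize an unphased pseudo-diploid call string: alleles sorted,
# "A/T" for hets, "A" for homozygotes, NA for missing.
canon_call <- function(a1, a2) {
  out <- ifelse(is.na(a1) | is.na(a2), NA_character_,
    ifelse(a1 == a2, a1,
      ifelse(a1 < a2, paste0(a1, "/", a2), paste0(a2, "/", a1))
    )
  )
  out
}

NUCS <- c("A", "C", "G", "T")
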