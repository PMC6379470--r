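# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages draw their seeds from a single top-level seed via
#' this function, so that an entire run is a pure function of one integer
#' while independent stages (expression, network, targets, null model) do
#' not share an RNG stream.
#'
#' @param seed Top-level integer seed.
#' @param offset Integer offset naming the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
sub_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # multiplicative hash kept in double precision; 2147483563 < 2^31
  as.integer((abs(seed) * 48271 + offset * 69621) %% 2147483563)
}

# Upper-case, trimmed gene symbols; the pipeline matches identifiers from
# several sources by symbol, so case is folded once at ingest.
norm_symbols <- function(x) toupper(trimws(as.character(x)))

stop_input <- function(...) stop(..., call. = FALSE)
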