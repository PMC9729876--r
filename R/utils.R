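#' Derive a per-stage child seed from a global seed
#'
#' One global seed fans out to independent stage seeds by fixed offsets so
#' that reruns of any single stage are reproducible in isolation. Offsets are
#' multiplied by a fixed odd stride and folded back into 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param offset Non-negative integer stage offset (0 = cohort generation,
#'   1 = trait generation, 2 = representative-case k-means, 3 = stochastic
#'   simulation, 4+ free for callers).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset), offset >= 0)
  as.integer((as.double(seed) + as.double(offset) * 1000003) %% 2147483647)
}

# log2(FPKM + 1) with the pipeline-wide pseudocount of 1
log2p1 <- function(x) log2(x + 1)

# inverse transform, floored at zero FPKM
inv_log2p1 <- function(y) pmax(2^y - 1, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)
warn_msg <- function(...) warning(sprintf(...), call. = FALSE)
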