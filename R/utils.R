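# Small shared helpers: proportion reporting, seed substreams, BH wrapper.

#' Report a count as a printed percentage
#'
#' Formats `count / total` as a percentage rounded to a fixed number of
#' decimal places, the convention used throughout the package's reported
#' summaries (e.g. "262 of 569 genomes (46.05%)").
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @param digits Decimal places to round to (default 2).
#' @return A numeric percentage, e.g. `pct(262, 569)` is `46.05`.
#' @export
#' @examples
#' pct(262, 569)
#' pct(314, 1591)
pct <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0, count >= 0)
  round(100 * count / total, digits)
}

#' Derive a deterministic sub-seed for a named component
#'
#' Fans one global seed out to independent named substreams so that, e.g.,
#' changing the number of gene families does not perturb the simulated tree.
#' The mapping is a fixed hash of the stream name mixed with the seed;
#' results stay within the 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65011L
  as.integer((abs(as.numeric(seed)) + h * 30011) %% 2147483587)
}

# Benjamini-Hochberg, kept as one call site for the whole package.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
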