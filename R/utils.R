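#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap list_rbind
NULL

# Deterministic 31-bit substream seed from a base seed plus string/integer
# labels, so each stochastic operation (and each contig within it) draws from
# its own reproducible stream without a hashing dependency.
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evenly spaced rank-based thinning: pick exactly n of m ranks, strictly
# increasing. Requires m >= n.
thin_ranks <- function(m, n) {
  if (m < n) abort("cannot thin: supply smaller than target")
  if (m == n) return(seq_len(m))
  floor(seq(0, m - 1, length.out = n)) + 1L
}

`%theninform%` <- function(cond, msg) {
  if (isTRUE(cond)) inform(msg)
  invisible(cond)
}
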