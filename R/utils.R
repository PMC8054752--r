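#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

logistic <- function(x) 1 / (1 + exp(-x))

# deterministic sub-seed in [1, 2^31 - 2] derived from a master seed and a
# character salt, so every model/stage is independently reproducible
derive_seed <- function(seed, salt) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste(salt, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' @export
generics::tidy

#' @export
generics::glance
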