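#' Clamp values to an interval
#' @noRd
clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

#' Stable 31-bit string hash
#'
#' Polynomial rolling hash used to derive per-rat RNG substreams from a
#' cohort seed, so adding rats to a design never perturbs the streams of
#' existing rats. Arithmetic stays below 2^53 so doubles are exact.
#' @noRd
stable_hash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  h
}

#' Derive a 31-bit substream seed from a base seed and a label
#' @noRd
substream_seed <- function(seed, label) {
  (stable_hash(label) + (seed %% 2147483647) * 10007) %% 2147483647
}

#' Draw from an exponential truncated to [0, upper)
#'
#' Inverse-CDF sampling; `scale` is the mean of the untruncated law.
#' @noRd
rtrunc_exp <- function(n, scale, upper) {
  u <- runif(n)
  -scale * log(1 - u * (1 - exp(-upper / scale)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
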