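# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit string hash (multiplicative, double arithmetic only so
# it is platform independent). Used to derive per-(repeat, subgroup) RNG seeds
# from one master seed: adding subgroups or repeats never perturbs the seeds
# of the others.
#' @noRd
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x, scientific = FALSE),
                                                 collapse = ","),
                    character(1)), collapse = "|")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 2147483629
  }
  as.integer(h)
}

# Largest-remainder apportionment of n units to target fractions.
# Ties in the fractional remainders are broken by position (first wins),
# which keeps the rule deterministic.
#' @noRd
largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  target <- n * fractions / sum(fractions)
  base <- floor(target)
  left <- round(n - sum(base))
  if (left > 0) {
    rem <- target - base
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' @noRd
subgroup_key <- function(values) paste(values, collapse = "|")

#' @noRd
subgroup_unkey <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

# Sample standard deviation with the n = 1 case mapped to 0 (flagged upstream).
#' @noRd
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' @noRd
stop_decreg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
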