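# Internal helpers shared across modules.

# Classed conditions so callers can distinguish configuration errors
# (bad parameters), input errors (bad data) and runtime failures.
pp_stop <- function(msg, class) {
  rlang::abort(msg, class = c(class, "permpath_error"))
}

stop_config <- function(msg) pp_stop(msg, "permpath_config_error")
stop_input <- function(msg) pp_stop(msg, "permpath_input_error")
stop_runtime <- function(msg) pp_stop(msg, "permpath_runtime_error")

# Deterministic per-stage / per-run seed streams derived from a base seed.
# Lehmer-style step keeps everything inside 32-bit integer range so the
# derived value is a legal `set.seed()` argument.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483399) + 1
  as.integer(((s * 48271 + as.numeric(stream) * 69621) %% 2147483399) + 1)
}

# log(sum(exp(x))) without overflow; empty input -> -Inf.
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
}

# Median of the 1-df chi-square distribution, the genomic-control denominator.
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)
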