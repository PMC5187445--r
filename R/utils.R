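#' @keywords internal
"_PACKAGE"

# Argument validation helpers -------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_invalid("`%s` must be >= %g", name, lower)
  if (x > upper)
    stop_invalid("`%s` must be <= %g", name, upper)
  invisible(x)
}

# Deterministic seed splitting ------------------------------------------------

#' Derive a child random seed from a master seed
#'
#' Counter-based seed splitting: a master seed plus a stream label and any
#' number of integer counters (trial index, electrode index, ...) map to a
#' reproducible child seed.  Subsets of a synthetic experiment are therefore
#' reproducible in isolation: trial 7 gets the same audio whether or not
#' trials 1-6 were generated first.
#'
#' @param master Master seed, a non-negative integer below 2^31.
#' @param ... Stream labels (strings) and integer counters, mixed in order.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629  # largest prime < 2^31; keeps products < 2^53 for doubles
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      codes <- utf8ToInt(paste(part, collapse = "|"))
    } else {
      codes <- as.numeric(part)
    }
    for (v in codes) {
      h <- (h * 69069 + (v %% m) + 1) %% m
    }
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small numeric helpers -------------------------------------------------------

next_pow2 <- function(n) 2^ceiling(log2(n))

rms <- function(x) sqrt(mean(x^2))

# FFT frequency axis in natural (unshifted) order
fft_freqs <- function(n, rate) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k * rate / n
}

# Analytic signal via frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

linear_resample <- function(x, from_rate, to_rate, n_out = NULL) {
  t_in <- (seq_along(x) - 1) / from_rate
  if (is.null(n_out)) n_out <- floor(length(x) * to_rate / from_rate)
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}
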