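# Internal helpers shared across modules.

# IUPAC nucleotide codes -> expansion over {A,C,G,T}.
iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

is_valid_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  length(chars) > 0 && all(chars %in% names(iupac_table()))
}

is_valid_dna <- function(x, allow_n = TRUE) {
  alphabet <- c("A", "C", "G", "T", if (allow_n) "N")
  chars <- strsplit(toupper(x), "")[[1]]
  length(chars) > 0 && all(chars %in% alphabet)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
# sdlog = sqrt(log(1 + cv^2)); meanlog = -sdlog^2/2 makes E[factor] = 1.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic child seed for stage `index` under global `seed` (kept < 2^31).
child_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 1e6) * 2011 + 17 * as.numeric(index)
  as.integer(s %% 2147483646 + 1)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s; got %s",
                  name,
                  if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]",
                  deparse(substitute(x))))
  }
  invisible(x)
}

assert_columns <- function(data, cols, name = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
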