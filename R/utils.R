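# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when one is supplied; otherwise use the
# current RNG stream unchanged.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Spearman correlation restricted to pairs where both values are nonzero and
# finite (the convention used throughout for score/degree correlations).
# Returns list(rho, n): rho is NA (never 0) when fewer than 3 qualifying pairs
# remain or when either variable is degenerate.
spearman_nonzero <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x != 0 & y != 0
  n <- sum(keep)
  if (n < 3L) {
    return(list(rho = NA_real_, n = n))
  }
  x <- x[keep]
  y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, n = n))
  }
  list(rho = stats::cor(x, y, method = "spearman"), n = n)
}

# Deterministic "top m" selection: ranks by value descending, ties broken by
# ascending identifier. Returns the selected identifiers.
top_m_by <- function(ids, values, m) {
  ord <- order(-values, ids)
  ids[ord][seq_len(min(m, length(ids)))]
}

stopifnot_scalar_prob <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x <= 1 && (if (open_left) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single probability in %s.",
                  name, if (open_left) "(0, 1]" else "[0, 1]"))
  }
  invisible(x)
}
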