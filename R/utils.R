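# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed; keeps results < 2^31.
#' @keywords internal
#' @noRd
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 69069 + 1234567 + as.double(k)) %% 2147483647
  as.integer(s)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shannon entropy (bits) of a set of probability masses; zero masses ignored.
#' @keywords internal
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# Minimal-overhead data.frame constructor for hot paths (no checks).
#' @keywords internal
#' @noRd
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

# Split a data frame into a list of row-lists without data.frame indexing
# overhead (hot loops over schedules).
#' @keywords internal
#' @noRd
df_rows <- function(df) {
  cols <- as.list(df)
  lapply(seq_len(nrow(df)), function(i) lapply(cols, `[[`, i))
}

# Truncated-normal draws by inverse-CDF.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
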