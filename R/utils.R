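#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# stop() with a consistent "configuration error" style message
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    config_error(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    config_error(field, sprintf("must be a single finite number in [%g, %g]", lo, hi))
  as.numeric(x)
}

# run code under a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# sample standard deviation / standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# 384-well style identifiers (row letter + 2-digit column) when the plate
# geometry allows, otherwise a plain numeric id
well_names <- function(plate_size) {
  if (plate_size == 384L) {
    rows <- LETTERS[1:16]
    as.vector(t(outer(rows, 1:24, function(r, c) sprintf("%s%02d", r, c))))
  } else if (plate_size == 96L) {
    rows <- LETTERS[1:8]
    as.vector(t(outer(rows, 1:12, function(r, c) sprintf("%s%02d", r, c))))
  } else {
    sprintf("W%03d", seq_len(plate_size))
  }
}

# significance stars at the conventional cutoffs
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
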