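# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_dims <- function(what, expected, actual) {
  stop(sprintf("%s: expected %s, got %s", what,
               paste(expected, collapse = " x "),
               paste(actual, collapse = " x ")), call. = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Half-up rounding (R's round() is half-to-even, which would starve odd
# class sizes of their test sample under an 0.2 fraction).
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
check_pm1 <- function(y, what = "y") {
  if (!all(y %in% c(-1, 1))) {
    stop(sprintf("%s must contain only +1 and -1 (found: %s)", what,
                 paste(utils::head(setdiff(unique(y), c(-1, 1)), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Format doubles so they round-trip exactly through text.
#' @noRd
format_full <- function(x) sprintf("%.17g", x)
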