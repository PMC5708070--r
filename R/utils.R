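`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a local random seed
#'
#' Sets the seed, runs `code`, and restores the caller's random-number
#' state, so seeded generators do not perturb the global stream.
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(..., call. = FALSE) stop(..., call. = call.)

# Conventional half-up rounding for displayed figures; base round() uses
# round-half-even, which disagrees with printed reference figures on .5 ties.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_input(sprintf("`%s` must be a probability in [0, 1]; got %s",
                       name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_input(sprintf("`%s` must be strictly positive; got %s",
                       name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_input(sprintf("`%s` must be non-negative; got %s",
                       name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(sprintf("%s is missing column(s): %s",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
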