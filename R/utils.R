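# Internal helpers: seed management and small validators.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state on exit, so seeded simulation calls do not perturb the
#' caller's random stream.  `seed = NULL` evaluates `expr` on the current
#' stream unchanged, which lets nested generators stay reproducible under a
#' single master seed.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a label, used to derive one RNG stream per
# cohort from a master seed.
label_hash <- function(x) {
  vapply(as.character(x), function(s) {
    v <- utf8ToInt(s)
    as.integer(sum(v * seq_along(v)) %% 1000003L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a per-label sub-seed from a master seed
#'
#' @param master integer master seed.
#' @param label character label (for example a cohort name).
#' @return an integer in `[1, 2^31 - 2]`, deterministic in both arguments.
#' @export
stream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((abs(as.numeric(master)) + 104729 * label_hash(label)) %% 2147483629) + 1L
}

stop_if_not_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  if (!all(is.finite(x) & lo & hi)) {
    stop(sprintf("`%s` must lie in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
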