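#' @importFrom rlang %||% .data
#' @keywords internal
"_PACKAGE"

# Set the RNG seed for the duration of the calling function, restoring the
# caller's RNG state on exit so sibling stages draw independent, reproducible
# streams from their own explicit seeds.
local_seed <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- .GlobalEnv$.Random.seed
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr <- bquote({
    if (is.null(.(old))) {
      suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    } else {
      assign(".Random.seed", .(old), envir = .GlobalEnv)
    }
  })
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}

# Deterministic child seed for stage `k` of a run seeded with `seed`;
# kept below 2^31 so it is a valid R integer seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + 12289 * k) %% 2000000000)
}

# Seconds since midnight -> hms clock label.
secs_to_hms <- function(x) hms::hms(seconds = x)

# "HH:MM[:SS]" -> seconds since midnight.
clock_s <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(hms::as_hms(ifelse(nchar(x) == 5, paste0(x, ":00"), x)))
}
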