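# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Emit a timestamped log line
#'
#' Writes `[timestamp] LEVEL message` to standard error (via [message()]) and,
#' when `options(mrpipe.log_file=)` is set, appends it to that file. Set
#' `options(mrpipe.verbose = FALSE)` to silence console output; file logging
#' is unaffected.
#'
#' @param fmt [sprintf()] format string.
#' @param ... values interpolated into `fmt`.
#' @param level one of `"info"`, `"warn"`, `"error"`.
#' @return the formatted line, invisibly.
#' @export
mrp_log <- function(fmt, ..., level = "info") {
  line <- sprintf("[%s] %s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), sprintf(fmt, ...))
  log_file <- getOption("mrpipe.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE, sep = "")
  if (isTRUE(getOption("mrpipe.verbose", TRUE))) message(line)
  invisible(line)
}

# 95% two-sided normal quantile used for internal confidence intervals
z95 <- function() stats::qnorm(0.975)

stop_insufficient <- function(n, need, what) {
  stop(sprintf("insufficient instruments for %s: have %d, need at least %d",
               what, n, need), call. = FALSE)
}
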