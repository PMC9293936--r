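#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   across left_join inner_join bind_rows n n_distinct distinct pull rename
#'   if_else first last count slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile plogis qlogis rnorm runif rbinom rpois
#'   rlnorm setNames complete.cases pnorm dnorm qnorm uniroot optim sd
#' @importFrom utils head tail
NULL

# Internal condition helper: all icpdyn errors carry a class so the CLI can
# map them onto exit codes.
stop_icpdyn <- function(message, class = "icpdyn_error", ...) {
  rlang::abort(message, class = c(class, "icpdyn_error"), ...)
}

inform_counts <- function(..., quiet = FALSE) {
  if (!quiet) rlang::inform(paste0(...))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

`%na%` <- function(x, y) if (is.na(x)) y else x

# canonical signal spelling used throughout: lowercase
normalise_signal <- function(x) tolower(as.character(x))

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_icpdyn(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "icpdyn_data_error"
    )
  }
  invisible(df)
}
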