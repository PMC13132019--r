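#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n count across bind_rows
#'   row_number rename relocate pull if_else
#' @importFrom stats rbinom rnbinom runif rnorm rpois sd setNames
NULL

# size-safe sampling with replacement from the values of `x`
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic code in the package funnels through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Month arithmetic at day resolution: `date` minus `n` calendar months,
# clamping the day-of-month to the target month's length.
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + n
  yr <- m0 %/% 12L
  mo <- m0 %% 12L
  last_day <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[mo + 1L]
  leap <- (yr + 1900L) %% 4L == 0L & ((yr + 1900L) %% 100L != 0L | (yr + 1900L) %% 400L == 0L)
  last_day <- ifelse(mo == 1L & leap, 29L, last_day)
  lt$year <- yr
  lt$mon <- mo
  lt$mday <- pmin(lt$mday, last_day)
  as.Date(lt)
}

stopf <- function(fmt, ..., class = "qolforum_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stopf("`%s` must be numeric in [0, 1].", name)
  }
  invisible(x)
}

is_date <- function(x) inherits(x, "Date")
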