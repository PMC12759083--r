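# Internal helpers: error conditions, argument checks, polygon geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mitosense_config_error", "error", "condition")))
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mitosense_input_error", "error", "condition")))
}

stop_stat <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mitosense_stat_error", "error", "condition")))
}

stop_generation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mitosense_generation_error", "error", "condition")))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_config("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) stop_config("'%s' must be a single finite number in %s%s, %s%s",
                       name, if (strict_lower) "(" else "[", lower, upper,
                       if (strict_upper) ")" else "]")
  as.numeric(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) stop_config("'seed' is required (no silent default randomness)")
  check_count(seed, "seed", min = 0L)
}

#' @importFrom withr with_seed
with_sim_seed <- function(seed, code) withr::with_seed(seed, code)

# Points strictly inside a polygon (mgcv's C routine; boundary points excluded).
# poly: 2-column matrix of (x, y) vertices, open or closed.
#' @importFrom mgcv in.out
points_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, cbind(as.numeric(x), as.numeric(y)))
}

# Shoelace area (absolute), used to reject degenerate gate polygons.
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Pearson correlation with an exact +/-1 for perfectly collinear input
# (plain cor() can be one ulp off, which matters for identity checks).
pearson_r <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  d1 <- sum(dx * dx); d2 <- sum(dy * dy)
  if (d1 == 0 || d2 == 0) stop_stat("Pearson correlation undefined: constant input")
  num <- sum(dx * dy)
  if (num * num == d1 * d2) return(sign(num))
  max(-1, min(1, num / sqrt(d1 * d2)))
}
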