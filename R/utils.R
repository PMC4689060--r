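#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of row_number rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dgamma pnorm qnorm rgamma rnorm rpois runif rbinom sd
#'   var median coef vcov glm Gamma as.formula model.matrix optim setNames
#'   quantile cor logLik dist complete.cases fitted
NULL

# deterministic per-stage seed derived from a root seed and a stream name;
# kept below 2^31 - 1 so it is always a valid R integer seed
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) * 10007
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Euclidean distance from points (px, py) to segments (x1,y1)-(x2,y2);
# vectorised over both (recycled to a common length)
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- pmax(dx * dx + dy * dy, 1e-12)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# arc-position of the perpendicular foot of (px,py) on the segment, in metres
# from (x1,y1), clamped to [0, L]
proj_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len <- sqrt(dx * dx + dy * dy)
  if (len < 1e-12) {
    return(rep(0, length(px)))
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len
  pmin(len, pmax(0, t))
}
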