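#' @keywords internal
"_PACKAGE"

#' @useDynLib rdaunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom
#' @importFrom utils head tail write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so results are pure functions of their seed arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_interval <- function(x, field, len = 2) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    stop_config(field, sprintf("must be a finite numeric vector of length %d", len))
  }
  if (x[1] > x[2]) stop_config(field, "must satisfy min <= max")
  invisible(x)
}

is_binary_mask <- function(m) {
  is.numeric(m) && all(m %in% c(0, 1))
}

check_mask <- function(m, name = "mask") {
  if (!is_binary_mask(m)) {
    stop(sprintf("'%s' must contain only values 0 and 1", name), call. = FALSE)
  }
  invisible(m)
}

check_same_grid <- function(a, b, what = c("image", "mask")) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("'%s' and '%s' must share the same grid (got %s vs %s)",
                 what[1], what[2],
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(NULL)
}

# 4-connectivity binary erosion with zero padding outside the grid.
erode4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], 0)
  down <- rbind(0, m[-h, , drop = FALSE])
  left <- cbind(m[, -1, drop = FALSE], 0)
  right <- cbind(0, m[, -w, drop = FALSE])
  m * up * down * left * right
}

# Boundary pixels of a binary mask: the mask minus its 4-connectivity erosion.
boundary_mask <- function(m) {
  m - erode4(m)
}
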