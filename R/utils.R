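#' @importFrom stats approx cor lm mad median pt qt rnorm rpois runif sd
#'   t.test var coef optim quantile
#' @importFrom utils head tail
NULL

# Internal: run code with a fixed RNG seed, restoring RNG state afterwards.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_sdexa <- function(..., class = "sdexa_error") {
  rlang::abort(paste0(...), class = class)
}

#' 2D box-filter local sums
#'
#' Sliding-window sums over a matrix with a square window of radius `r`,
#' computed with summed-area tables. Windows are clipped at the borders;
#' `counts` gives the number of contributing pixels per position.
#'
#' @param x numeric matrix.
#' @param r integer window radius in pixels (window is `(2r+1)^2` clipped).
#' @return list with `sum` and `count` matrices of the same shape as `x`.
#' @keywords internal
box_sums <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(nr); j <- seq_len(nc)
  i0 <- pmax(i - r, 1); i1 <- pmin(i + r, nr)
  j0 <- pmax(j - r, 1); j1 <- pmin(j + r, nc)
  # sums over [i0..i1] x [j0..j1] via inclusion-exclusion on the SAT
  S <- sat[i1 + 1, j1 + 1, drop = FALSE] - sat[i0, j1 + 1, drop = FALSE] -
    sat[i1 + 1, j0, drop = FALSE] + sat[i0, j0, drop = FALSE]
  cnt <- outer(i1 - i0 + 1, j1 - j0 + 1)
  list(sum = S, count = cnt)
}

box_mean <- function(x, r) {
  b <- box_sums(x, r)
  b$sum / b$count
}

# Bilinear sampling of matrix `img` at (continuous, 1-based) coordinates.
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, ri, ci, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  # clamp for safe indexing; masked afterwards
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  idx <- function(r, c) (c - 1L) * nr + r
  v <- (1 - fr) * (1 - fc) * img[idx(r0c, c0c)] +
    fr * (1 - fc) * img[idx(r0c + 1, c0c)] +
    (1 - fr) * fc * img[idx(r0c, c0c + 1)] +
    fr * fc * img[idx(r0c + 1, c0c + 1)]
  v[!ok] <- fill
  v
}

# Nearest-neighbour sampling (for label maps).
nearest_sample <- function(img, ri, ci, fill = 0L) {
  nr <- nrow(img); nc <- ncol(img)
  r <- round(ri); c <- round(ci)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  rc <- pmin(pmax(r, 1), nr); cc <- pmin(pmax(c, 1), nc)
  v <- img[(cc - 1L) * nr + rc]
  v[!ok] <- fill
  v
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
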