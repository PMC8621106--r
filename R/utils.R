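# internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  })
  set.seed(seed)
  expr
}

# round half away from zero: printed percentages are commercial-rounded
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("smlmpipe_invalid_parameter", "error")))
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(name, " must be a single non-missing number")
  }
  if (strict && x <= min) stop_invalid(name, " must be > ", min)
  if (!strict && x < min) stop_invalid(name, " must be >= ", min)
  invisible(x)
}

# convex-hull area of a 2-column coordinate matrix (shoelace); NA if degenerate
hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(NA_real_)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a <= 0) NA_real_ else a
}
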