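#' @keywords internal
pcg_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pcgnet_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @keywords internal
pcg_assert <- function(cond, class, msg) {
  if (!isTRUE(cond)) pcg_error(class, msg, call = sys.call(-1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Best rational approximation p/q of a positive real by continued fractions,
# with denominator capped. Used for polyphase resampling ratios.
#' @keywords internal
rational_approx <- function(x, max_den = 1000L) {
  stopifnot(x > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  if (p1 < 1) { p1 <- 1 }
  c(p = as.integer(p1), q = as.integer(q1))
}

# Evaluate the RNG-dependent expression under a local, seeded RNG stream,
# restoring the caller's RNG state afterwards.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed derived from a master seed; stays inside the
# 32-bit signed integer range R requires of set.seed().
#' @keywords internal
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 1009 + as.double(k) * 9973) %% 2147483647)
}
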