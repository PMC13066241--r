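# Internal helpers shared across the package.

#' @noRd
rot2 <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(c_, s_, -s_, c_), 2L, 2L)
}

# planar 90-degree rotation (d/dphi of rot2 applied to a vector)
#' @noRd
perp2 <- function(v) c(-v[2L], v[1L])

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x))
    axis <- c("x", "y", "z")[(bad[1L] - 1L) %% 3L + 1L]
    stopf("non-finite value in %s (axis %s)", what, axis)
  }
  invisible(x)
}

# Run expr with a deterministic RNG stream without disturbing the caller's.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Recursively merge user list into defaults, rejecting keys that the
# defaults do not know about (typo protection for configuration files).
#' @noRd
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stopf("unknown configuration key%s: %s",
          if (length(unknown) > 1L) "s" else "",
          paste0(path, unknown, collapse = ", "))
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   paste0(path, nm, "."))
  defaults
}

# Periodic linear interpolation on [0, period).
#' @noRd
interp_cyclic <- function(t, period, x, y) {
  tt <- t %% period
  stats::approx(x, y, xout = tt, rule = 2)$y
}
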