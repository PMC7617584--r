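# Internal helpers: local RNG scoping, derived-seed common-random-number streams.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions taking a `seed`
#' argument do not disturb the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# registry of named simulation processes; index feeds the derived stream seed
.PROCESSES <- c(
  "align", "mortality", "health", "ltsick", "education", "wage",
  "labour_gumbel", "pandemic_transition", "pandemic_hours", "new_hours",
  "mh_step1", "mh_caseness", "misc"
)

#' Derived seed for a (year, process) stream
#' @noRd
stream_seed <- function(base_seed, year, process) {
  pid <- match(process, .PROCESSES)
  if (is.na(pid)) stop("unknown process stream: ", process)
  s <- (as.double(base_seed) * 48271 + as.double(year) * 1299721 + pid * 69621) %%
    2147483629
  as.integer(s) + 1L
}

#' Common-random-number uniforms keyed by stable entity id
#'
#' Draws one uniform per entity for the given (year, process) stream and
#' assigns them in increasing-id order, so the numbers a given entity receives
#' do not depend on row order and are shared across paired scenario arms that
#' hold the same id set.
#' @noRd
crn_runif <- function(ids, base_seed, year, process, k = 1L) {
  n <- length(ids)
  o <- order(ids)
  if (k == 1L) {
    u <- numeric(n)
    u[o] <- with_seed(stream_seed(base_seed, year, process), stats::runif(n))
    u
  } else {
    m <- matrix(0, n, k)
    m[o, ] <- with_seed(stream_seed(base_seed, year, process),
                        matrix(stats::runif(n * k), n, k))
    m
  }
}

#' Normal CRN draws, same keying as crn_runif
#' @noRd
crn_rnorm <- function(ids, base_seed, year, process, sd = 1) {
  n <- length(ids)
  o <- order(ids)
  z <- numeric(n)
  z[o] <- with_seed(stream_seed(base_seed, year, process), stats::rnorm(n, 0, 1))
  z * sd
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
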