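#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' A single run seed is turned into independent per-stage seeds so that
#' individual pipeline stages can be re-run in isolation and still draw the
#' same random numbers as inside a full run. The derivation is a small
#' deterministic integer hash; it involves no RNG state itself.
#'
#' @param seed Master integer seed.
#' @param tag Character stage label (e.g. `"de_rna"`, `"null_test"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(tag)) {
    h <- (h * 31 + k) %% m
  }
  # multiplicative scramble keeps nearby seeds apart
  h <- (h * 48271) %% m
  as.integer(max(h, 1))
}

#' @keywords internal
with_seed <- function(seed, expr) {
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

#' @keywords internal
pv_log <- function(...) {
  if (isTRUE(getOption("parallevol.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[parallevol %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a named
#' surface so every stage adjusts p-values the same way. `NA` p-values (e.g.
#' non-converged fits) stay `NA` and do not count toward the number of tests.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
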