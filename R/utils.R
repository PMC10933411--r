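#' @keywords internal
"_PACKAGE"

#' @useDynLib coevclade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

## 21-state alphabet used everywhere: 20 amino acids + gap as the last state.
COEV_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
COEV_Q <- 21L

coev_stop <- function(msg, class = "coev_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "coev_error")))
}

coev_warn <- function(msg, class = "coev_warning") {
  warning(warningCondition(msg, class = c(class, "coev_condition")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Seeds R's RNG for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
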