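# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "recallsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive the RNG seed for one replicate
#'
#' Each replicate's random stream is a pure function of the master seed and
#' the replicate index, so any single replicate can be regenerated without
#' rerunning its predecessors. Seeds are kept below 2^31 - 1.
#'
#' @param master_seed Integer master seed for the whole run.
#' @param i Replicate index (1-based).
#' @return An integer seed suitable for [set.seed()].
#' @export
replicate_seed <- function(master_seed, i) {
  if (!is_count(abs(master_seed))) stop_invalid("invalid_seed", "master_seed must be an integer")
  if (!is_count(i) || i < 1) stop_invalid("invalid_seed", "replicate index must be a positive integer")
  m <- 2147483647 # 2^31 - 1, prime
  base <- as.numeric(master_seed) %% m
  # Lehmer-style mix; products stay below 2^53 so doubles are exact
  s <- (base * 48271) %% m
  s <- (s + (as.numeric(i) * 16807) %% m) %% m
  as.integer(s)
}

# evaluate code with a local, restored RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
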