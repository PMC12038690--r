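# Shared validation and small helpers

stop_if_not <- function(cond, msg, class = "pegs_invalid_parameter") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "pegs_error")))
  }
  invisible(TRUE)
}

pegs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pegs_error")))
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards.  With seed = NULL the expression runs on the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
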