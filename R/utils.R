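# Internal helpers shared across modules.

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_config <- function(...) {
  stop(structure(class = c("erdlia_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("erdlia_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schedule <- function(...) {
  stop(structure(class = c("erdlia_schedule_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
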