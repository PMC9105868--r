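#' @keywords internal
"_PACKAGE"

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# All randomness in the package goes through this so that no function
# perturbs (or depends on) the global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("sensorprune_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sensorprune_config_error", "error")))
}
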