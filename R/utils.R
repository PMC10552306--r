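# internal helpers

.datatable.aware <- TRUE

# run `expr` under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# fan-in scaled uniform initialization
init_uniform <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(max(1, fan_in))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# per-column fan-in initialization for a masked G x P weight matrix
init_masked <- function(mask) {
  fan <- pmax(1, colSums(mask))
  U <- matrix(0, nrow(mask), ncol(mask))
  for (j in seq_len(ncol(mask))) {
    lim <- 1 / sqrt(fan[j])
    U[, j] <- runif(nrow(mask), -lim, lim) * mask[, j]
  }
  U
}
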