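# Small fixtures built in code at test time.

make_mixture <- function(k = 4, d = 5, n = 2000, sep = 8, seed = 1) {
  gen_mixture(mixture_spec(k = k, d = d, n = n, separation = sep, seed = seed))
}

# a small but complete seeded end-to-end run, shared across test files
small_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- make_mixture(k = 3, d = 4, n = 3000, sep = 8, seed = 11)
      res <- flowsom(sim$frame, n_meta = 3, xdim = 4, ydim = 4, rlen = 5,
                     seed = 5)
      cache <<- list(result = res, truth = sim$truth)
    }
    cache
  }
})

# run the installed CLI script in a fresh R process
run_cli <- function(args) {
  script <- system.file("cli", "cytosom", package = "cytosom")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- suppressWarnings(system2(
    "Rscript", c(shQuote(script), vapply(args, shQuote, character(1))),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", libs)))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_unit_interval <- function(x) {
  expect_true(all(x >= 0 & x <= 1))
}
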