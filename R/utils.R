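## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glyco <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_glyco(...)
  invisible(TRUE)
}

#' Derive a stream-specific RNG seed from a master seed
#'
#' All stochastic stages draw their seed from one master integer so that a
#' single `--seed` reproduces every artifact. Kept below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param stream small non-negative integer identifying the consumer
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483647)
}

peak_names <- function(panel) {
  switch(match.arg(panel, c("plasma", "igg")),
    plasma = paste0("GP", 1:39),
    igg = paste0("IGP", 1:24)
  )
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "glycopd")
  if (!nzchar(p)) stop_glyco("bundled data file not found: %s", file)
  p
}
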