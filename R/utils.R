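# Structured conditions and logging shared across modules.

# error classes: sbml_parse_error, sbml_semantic_error,
# sbml_unsupported_error, sbml_numeric_error, sbml_cycle_error
stop_sbml <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("sbml_", class, "_error"), "sbml_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

# lightweight leveled logging to stderr; controlled by
# options(sbmlsim.verbose = TRUE) or the CLI -v flag
sbml_log <- function(..., level = "info") {
  if (isTRUE(getOption("sbmlsim.verbose", FALSE)) || level == "warn")
    message("[sbmlsim ", level, "] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# machine tolerance used when clamping steps onto output/event times
time_eps <- function(duration) duration * 1e-12
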