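# internal helpers

# Run `code` under a local seed without touching the caller's RNG state;
# seed = NULL means "use the current stream".
.withSeed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# 17 significant digits round-trips IEEE doubles through text exactly.
.fmtNum <- function(x) sprintf("%.17g", x)

.assertScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("'", name, "' must be > 0", call. = FALSE)
  }
  invisible(x)
}

.validateGroupLabels <- function(groups) {
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("group assignment must be a named vector with unique sample ids",
         call. = FALSE)
  }
  bad <- setdiff(unique(groups), c("RG", "MSG"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'RG' or 'MSG')", call. = FALSE)
  }
  if (!any(groups == "RG") || !any(groups == "MSG")) {
    stop("both groups 'RG' and 'MSG' must be non-empty", call. = FALSE)
  }
  invisible(groups)
}
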