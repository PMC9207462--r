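# Internal helpers shared across modules.

# Standard deviation under the configured convention.
# mode "sample" = n-1 denominator, "population" = n denominator.
sd_by_mode <- function(x, mode = c("sample", "population")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  if (mode == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
}

# Geometric mean; x must be strictly positive.
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  exp(mean(log(x)))
}

# Timestamped log line to stderr, gated by options(refstab.verbose).
refstab_log <- function(..., level = 1L) {
  verb <- getOption("refstab.verbose", 0L)
  if (verb >= level) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "[refstab] ", ...)
  }
  invisible(NULL)
}

# Collapse a character vector for error messages.
quoted_list <- function(x) paste(sprintf("'%s'", x), collapse = ", ")
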