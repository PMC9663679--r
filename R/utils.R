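# Internal helpers shared across the package.

# Percentage of x out of n, rounded to one decimal with R's IEC 60559
# round-half-to-even — the convention the published tables follow (e.g.
# 13/80 prints as 16.2, 33/80 as 41.2).
pct1 <- function(x, n) round(100 * x / n, 1)

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_gbs_range <- function(gbs, name = "gbs") {
  if (any(is.na(gbs)) || any(gbs != round(gbs)) ||
      any(gbs < 0) || any(gbs > 23)) {
    stop(sprintf("'%s' must contain integers in [0, 23]", name),
         call. = FALSE)
  }
  invisible(as.integer(gbs))
}

as_logical_01 <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1) | is.na(x))) return(x == 1)
  if (is.character(x)) {
    lo <- tolower(x)
    if (all(lo %in% c("0", "1", "true", "false", "") | is.na(x))) {
      out <- lo %in% c("1", "true")
      out[is.na(x) | lo == ""] <- NA
      return(out)
    }
  }
  stop(sprintf("column '%s' must be logical or coded 0/1", name),
       call. = FALSE)
}
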