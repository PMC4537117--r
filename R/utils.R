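# Internal helpers shared across modules.

# Round half away from zero, as tables of percentages are conventionally
# printed. base::round() rounds half to even, which would turn e.g. an exact
# 99.955 into 99.96 or 99.95 depending on the binary representation.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic child seed: runs a block under a seed derived from `seed` and
# an integer offset, restoring the caller's RNG state afterwards. All
# generators are pure functions of (inputs, seed) through this.
with_seed <- function(seed, offset = 0L, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

stop_paneldx <- function(msg, class, ...) {
  abort(msg, class = c(class, "paneldx_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_paneldx(
      sprintf("`%s` must be a single number in [%s, %s], got %s",
              name, format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      class = "paneldx_validation_error"
    )
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_paneldx(
      sprintf("%s is missing mandatory column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "paneldx_schema_error"
    )
  }
  invisible(df)
}

AUTOSOMES <- paste0("chr", 1:22)
SEX_CHROMS <- c("chrX", "chrY")
KNOWN_CHROMS <- c(AUTOSOMES, SEX_CHROMS, "chrM")

is_autosome <- function(chrom) chrom %in% AUTOSOMES

normalize_chrom <- function(chrom) {
  out <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  bad <- setdiff(unique(out), KNOWN_CHROMS)
  if (length(bad) > 0) {
    stop_paneldx(
      sprintf("unknown chromosome name(s): %s", paste(bad, collapse = ", ")),
      class = "paneldx_validation_error"
    )
  }
  out
}
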