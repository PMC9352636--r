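#' Round half away from zero at a given number of decimals
#'
#' Decimal rounding with ties going up (0.25 -> 0.3 at one decimal), the
#' convention used for the reported tables. Base R's `round()` rounds half to
#' even. A 1e-9 relative guard absorbs binary floating-point representation
#' error (e.g. a value stored as 4618.49999999995 that is arithmetically
#' 4618.5).
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Convert an oral dose in mg to µmol
#'
#' @param mg dose in mg
#' @param mw molecular weight in g/mol
#' @return dose in µmol
#' @export
mg_to_umol <- function(mg, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  mg / mw * 1000
}

# get/set a value in a nested list by a dotted path like "ba.Gdose"
get_path <- function(lst, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (is.null(lst[[k]])) stop(sprintf("unknown parameter path '%s'", path))
    lst <- lst[[k]]
  }
  lst
}

set_path <- function(lst, path, value) {
  if (is.numeric(value)) value <- unname(value)
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  lst[[keys[1]]] <- set_path(lst[[keys[1]]],
                             paste(keys[-1], collapse = "."), value)
  lst
}

`%||%` <- function(a, b) if (is.null(a)) b else a
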