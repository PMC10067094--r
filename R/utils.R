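#' @keywords internal
"_PACKAGE"

# Standard one-letter amino-acid alphabet; "*" is the normalized stop symbol.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_SYMBOL <- "*"

#' Round half away from zero
#'
#' Percentages in cohort summaries are printed to one decimal with
#' conventional half-up rounding (base [round] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Read a tab-delimited table with a header, failing loudly on malformed input.
read_tsv_checked <- function(path, required = character(), what = "table") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read ", what, ": file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) {
      stop("cannot parse ", what, " '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("parse error in ", what, " '", path, "': missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "tp53ea", mustWork = TRUE)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
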