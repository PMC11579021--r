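# Internal helpers shared across modules.

#' Reverse-complement a nucleotide string
#'
#' Vectorised over its input. Accepts A/C/G/T/N (case-insensitive); any
#' other symbol is an error.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements, upper case.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    cv <- .comp_table[utf8ToInt(s)]
    if (anyNA(cv)) stop("non-ACGTN symbols in sequence")
    intToUtf8(rev(cv))
  }, character(1), USE.NAMES = FALSE)
}

.comp_table <- {
  tb <- rep(NA_integer_, 128)
  from <- utf8ToInt("ACGTNacgtn")
  to <- utf8ToInt("TGCANTGCAN")
  tb[from] <- to
  tb
}

# seed streams: one per output family so regenerating one family does not
# perturb the others; all derived seeds stay below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(genome = 11L, annotation = 23L, expression = 37L,
               events = 53L, report = 71L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stream]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-open-free overlap on 1-based inclusive intervals
overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# Write a tibble as TSV without extra dependencies beyond utils.
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(name, " must be non-negative")
  }
  invisible(x)
}
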