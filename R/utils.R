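#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_fmt <- function(fmt, ..., class = "neuroinduct_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

config_error <- function(fmt, ...) stop_fmt(fmt, ..., class = "neuroinduct_config_error")
format_error <- function(fmt, ...) stop_fmt(fmt, ..., class = "neuroinduct_format_error")

## Deterministic sub-seeds: each generator draws from seed + a fixed offset so
## that components can be regenerated independently and still match a full run.
## Offsets stay far below .Machine$integer.max.
sub_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + offset) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

pkg_version_string <- function() {
  as.character(utils::packageVersion("neuroinduct"))
}

## Header comment written at the top of every tab-delimited output.
tsv_header_comment <- function(params = NULL) {
  line <- sprintf("# neuroinduct %s", pkg_version_string())
  if (!is.null(params) && length(params)) {
    kv <- paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                      character(1)), sep = "=", collapse = " ")
    line <- c(line, paste("#", kv))
  }
  line
}
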