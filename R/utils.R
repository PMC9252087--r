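# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lower-case alphanumeric tokens of a free-text string
tokenize <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

# does the keyword's token sequence occur contiguously in the text's tokens?
keyword_matches <- function(keyword, text) {
  kw <- tokenize(keyword)[[1]]
  tx <- tokenize(text)[[1]]
  nk <- length(kw); nt <- length(tx)
  if (nk == 0L || nt < nk) return(FALSE)
  for (i in seq_len(nt - nk + 1L)) {
    if (all(tx[i:(i + nk - 1L)] == kw)) return(TRUE)
  }
  FALSE
}

# validate a rules table (columns family, keyword); returns normalised df
check_family_rules <- function(family_rules) {
  if (!is.data.frame(family_rules) ||
      !all(c("family", "keyword") %in% names(family_rules)))
    stop("family_rules must be a data.frame with columns 'family' and 'keyword'")
  if (nrow(family_rules) == 0L) stop("family_rules is empty")
  data.frame(family = as.character(family_rules$family),
             keyword = as.character(family_rules$keyword),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
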