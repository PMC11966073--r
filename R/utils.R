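# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an entity name for matching
#'
#' Lower-cases, trims, and collapses internal whitespace. This is the
#' normalization applied before any "identical term name" comparison during
#' integration and before name-index lookups.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
norm_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Pipe-joined list fields used in the delimited bulk/source formats.
join_pipe <- function(x) {
  if (length(x) == 0) return("")
  if (any(grepl("[|\t\n]", x)))
    stop("field value contains a reserved delimiter character ('|' or tab)")
  paste(x, collapse = "|")
}

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

# Safe lookup in a named character vector of attributes.
attr_get <- function(a, k) {
  if (length(a) && k %in% names(a)) a[[k]] else NA_character_
}

# Stable key for a (type, normalized name) pair in the name index.
name_key <- function(type, name) paste(type, norm_name(name), sep = "\t")

stop_suppkb <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "suppkb_error")))
}
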