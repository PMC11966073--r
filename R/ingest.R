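#' @title Source-record ingestion and cleaning
#' @description
#' Readers for the three source dialects (product, ingredient, assertion
#' records as delimited text), the nonsense-name cleaning filter, field
#' variant unification via an alias table, and synonym grouping by shared
#' group id. Malformed rows are rejected and logged per row; they never abort
#' a build.
#' @name ingest
NULL

# Required columns per dialect; remaining columns are optional.
dialect_columns <- function(dialect) {
  switch(dialect,
    product = list(required = c("product_name", "company_name"),
                   optional = c("company_address", "purpose", "risk",
                                "ingredients")),
    ingredient = list(required = "name",
                      optional = c("synonyms", "group_id", "background",
                                   "safety", "mechanism_of_action",
                                   "source_material", "cui")),
    assertion = list(required = c("subject_name", "object_name",
                                  "object_category"),
                     optional = c("rating", "sentence", "subject_cui",
                                  "object_cui")),
    stop_suppkb("unknown dialect '%s'", dialect, class = "suppkb_bad_dialect"))
}

#' Map an assertion object category to a concept type
#' @param category One of "disease", "drug", "symptom", "therapeutic class",
#'   "organ system".
#' @return A concept type code.
#' @export
category_concept_type <- function(category) {
  m <- c(disease = "DISEASE", drug = "DRUG", symptom = "SYMPTOM",
         `therapeutic class` = "TC", `organ system` = "SOC")
  ty <- m[norm_name(category)]
  if (is.na(ty))
    stop_suppkb("unknown assertion object category '%s'", category,
                class = "suppkb_bad_category")
  unname(ty)
}

opt_field <- function(row, col) {
  v <- row[[col]]
  if (is.null(v) || is.na(v) || !nzchar(trimws(v))) NA_character_
  else trimws(v)
}

#' Read a source-record file
#'
#' Parses a delimited UTF-8 file (header row) in one of the three dialects.
#' Every row is either parsed into a record or rejected with a logged reason;
#' `n_parsed + n_rejected` always equals the number of data rows.
#'
#' @param path File path.
#' @param dialect One of `"product"`, `"ingredient"`, `"assertion"`.
#' @param source Source-database label attached to every record.
#' @param delim Field delimiter (default tab).
#' @return A list with `records` (list of named-list records, each carrying
#'   `source`), `rejected` (data.frame of `line`, `reason`), `n_parsed`,
#'   `n_rejected`.
#' @export
read_source <- function(path, dialect, source, delim = "\t") {
  cols <- dialect_columns(dialect)
  if (!file.exists(path))
    stop_suppkb("source file '%s' does not exist", path,
                class = "suppkb_missing_file")
  df <- tryCatch(
    utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = character(0),
                      quote = "", check.names = FALSE),
    error = function(e)
      stop_suppkb("cannot parse '%s': %s", path, conditionMessage(e),
                  class = "suppkb_parse_error"))
  missing_cols <- setdiff(cols$required, names(df))
  if (length(missing_cols))
    stop_suppkb("source file '%s' lacks required column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "suppkb_parse_error")
  records <- list()
  rejected <- list()
  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, , drop = FALSE])
    bad <- cols$required[vapply(cols$required, function(cn)
      is.na(opt_field(row, cn)), logical(1))]
    if (length(bad)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(line = i + 1L,
                   reason = sprintf("missing required field(s): %s",
                                    paste(bad, collapse = ", ")),
                   stringsAsFactors = FALSE)
      next
    }
    rec <- switch(dialect,
      product = list(
        source = source,
        product_name = opt_field(row, "product_name"),
        company_name = opt_field(row, "company_name"),
        company_address = opt_field(row, "company_address"),
        purpose = opt_field(row, "purpose"),
        risk = opt_field(row, "risk"),
        ingredient_names = split_pipe(opt_field(row, "ingredients") %||%
                                        NA_character_)),
      ingredient = list(
        source = source,
        name = opt_field(row, "name"),
        synonyms = split_pipe(opt_field(row, "synonyms") %||% NA_character_),
        group_id = opt_field(row, "group_id"),
        background = opt_field(row, "background"),
        safety = opt_field(row, "safety"),
        mechanism_of_action = opt_field(row, "mechanism_of_action"),
        source_material = opt_field(row, "source_material"),
        cui = opt_field(row, "cui")),
      assertion = {
        cat_raw <- opt_field(row, "object_category")
        ty <- tryCatch(category_concept_type(cat_raw), error = function(e) NULL)
        if (is.null(ty)) {
          rejected[[length(rejected) + 1L]] <-
            data.frame(line = i + 1L,
                       reason = sprintf("unknown object_category '%s'",
                                        cat_raw),
                       stringsAsFactors = FALSE)
          next
        }
        list(
          source = source,
          subject_name = opt_field(row, "subject_name"),
          object_name = opt_field(row, "object_name"),
          object_category = ty,
          rating_text = opt_field(row, "rating"),
          sentence = opt_field(row, "sentence"),
          subject_cui = opt_field(row, "subject_cui"),
          object_cui = opt_field(row, "object_cui"))
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected)
    else data.frame(line = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  list(records = records, rejected = rejected,
       n_parsed = length(records), n_rejected = nrow(rejected))
}

#' Keep/drop filter for nonsense ingredient names
#'
#' A name is dropped when, after trimming, it has fewer than two characters or
#' consists solely of digits, punctuation/symbols, and whitespace. Covers
#' noise entries such as "8" or "%.". Extra drop patterns can be supplied as
#' Perl regular expressions (configuration, not hard-coded rules).
#'
#' @param name Character vector of candidate names.
#' @param extra_patterns Optional character vector of additional Perl regexes;
#'   a match drops the name.
#' @return Logical vector: `TRUE` to keep, `FALSE` to drop.
#' @examples
#' clean_ingredient_name(c("8", "%", "Acacia", "B6"))
#' @export
clean_ingredient_name <- function(name, extra_patterns = character(0)) {
  x <- trimws(as.character(name))
  keep <- nchar(x) >= 2 &
    !grepl("^[\\p{N}\\p{P}\\p{S}\\s]*$", x, perl = TRUE)
  for (p in extra_patterns)
    keep <- keep & !grepl(p, x, perl = TRUE)
  keep
}

#' Unify recorded field variants against an alias table
#'
#' Maps each value through a variant-to-canonical alias table (the
#' deterministic stand-in for model-assisted unification of, e.g., country
#' spellings in company addresses). Unknown values pass through unchanged and
#' are reported.
#'
#' @param values Character vector.
#' @param alias_table Named character vector: `names()` are variants, values
#'   are canonical forms.
#' @return A list with `values` (canonicalized vector, same length) and
#'   `unmatched` (unique values not found in the table).
#' @export
unify_field_variants <- function(values, alias_table) {
  values <- as.character(values)
  hit <- values %in% names(alias_table)
  out <- values
  out[hit] <- unname(alias_table[values[hit]])
  list(values = out,
       unmatched = sort(unique(values[!hit & !is.na(values)])))
}

#' Group ingredient records by shared group id
#'
#' Records sharing a `group_id` collapse into one synonym group whose name set
#' is the union of member names and synonyms; records without a group id form
#' singleton groups. Group attributes take the first-seen non-missing value
#' per key; conflicting later values are logged, first-seen wins.
#'
#' @param records List of ingredient records (as produced by [read_source()]
#'   with dialect `"ingredient"`).
#' @return A list with `groups` (list of group records: `names`, `group_id`,
#'   `cui`, `source`, `sources`, `attributes`, `member_idx`) and `conflicts`
#'   (character log). The groups partition the input records.
#' @export
group_synonyms <- function(records) {
  groups <- list()
  key_of <- list()  # group_id -> index into groups
  conflicts <- character(0)
  attr_keys <- c(background = "background", safety = "safety",
                 mechanism_of_action = "mechanism_of_action",
                 source_material = "source_material")
  for (i in seq_along(records)) {
    rec <- records[[i]]
    gid <- rec$group_id
    idx <- if (!is.na(gid %||% NA_character_) && gid %in% names(key_of))
      key_of[[gid]] else NA_integer_
    rec_names <- unique(c(rec$name, rec$synonyms))
    rec_attrs <- character(0)
    for (k in attr_keys) {
      v <- rec[[k]]
      if (!is.null(v) && !is.na(v)) rec_attrs[[k]] <- v
    }
    if (is.na(idx)) {
      groups[[length(groups) + 1L]] <- list(
        names = rec_names, group_id = gid %||% NA_character_,
        cui = rec$cui %||% NA_character_,
        source = rec$source, sources = rec$source,
        attributes = rec_attrs, member_idx = i)
      if (!is.na(gid %||% NA_character_))
        key_of[[gid]] <- length(groups)
    } else {
      grp <- groups[[idx]]
      grp$names <- unique(c(grp$names, rec_names))
      grp$sources <- unique(c(grp$sources, rec$source))
      grp$member_idx <- c(grp$member_idx, i)
      rc <- rec$cui %||% NA_character_
      if (is.na(grp$cui)) grp$cui <- rc
      else if (!is.na(rc) && rc != grp$cui)
        conflicts <- c(conflicts, sprintf(
          "group '%s': conflicting cui '%s' vs first-seen '%s' (kept first)",
          gid, rc, grp$cui))
      for (k in names(rec_attrs)) {
        if (!(k %in% names(grp$attributes)))
          grp$attributes[[k]] <- rec_attrs[[k]]
        else if (grp$attributes[[k]] != rec_attrs[[k]])
          conflicts <- c(conflicts, sprintf(
            "group '%s': conflicting %s (kept first)", gid, k))
      }
      groups[[idx]] <- grp
    }
  }
  list(groups = groups, conflicts = conflicts)
}
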