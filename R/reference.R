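#' Published knowledge-base count table
#'
#' The published per-row concept, relationship and attribute counts of the
#' full-scale knowledge base, with the totals the publication prints. Used to
#' check the table's internal arithmetic with [totals_report()]; this
#' package's synthetic builds make no attempt to reproduce these magnitudes.
#'
#' @return A list with `rows` (data.frame `section`, `label`, `count`) and
#'   `printed_totals` (named vector: `concepts`, `relations`, `attributes`).
#' @export
idisk2_reference_counts <- function() {
  f <- system.file("extdata", "idisk2_table1.csv", package = "suppkb",
                   mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  totals <- df[grepl("_total$", df$section), ]
  rows <- df[!grepl("_total$", df$section), ]
  list(rows = rows,
       printed_totals = c(
         concepts = totals$count[totals$section == "concept_total"],
         relations = totals$count[totals$section == "relationship_total"],
         attributes = totals$count[totals$section == "attribute_total"]))
}

#' Published evaluation question-bank counts
#'
#' Per-category counts of the published true-or-false and multiple-choice
#' question banks, with the printed per-kind totals.
#'
#' @return A list with `rows` (data.frame `kind`, `category`, `count`) and
#'   `printed_totals` (named vector: `TF`, `MCQ`).
#' @export
idisk2_question_bank <- function() {
  f <- system.file("extdata", "question_bank.csv", package = "suppkb",
                   mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  totals <- df[grepl("_total$", df$kind), ]
  rows <- df[!grepl("_total$", df$kind), ]
  list(rows = rows,
       printed_totals = c(TF = totals$count[totals$kind == "TF_total"],
                          MCQ = totals$count[totals$kind == "MCQ_total"]))
}
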