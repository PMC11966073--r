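#' Emit openCypher MERGE statements for a graph
#'
#' Live-backend adapter: renders every concept and triple as an idempotent
#' `MERGE` statement suitable for piping into a graph-database shell. Nothing
#' in the package requires a running server; the bulk CSV tables
#' ([kg_export_bulk()]) are the primary deployment path.
#'
#' @param g A `kg` object.
#' @return Character vector of Cypher statements, concepts first.
#' @export
kg_cypher_statements <- function(g) {
  esc <- function(x) gsub("'", "\\\\'", x)
  stmts <- character(0)
  for (id in kg_concept_ids(g)) {
    cp <- g$concepts[[id]]
    props <- sprintf("idisk_id: '%s', preferred_name: '%s'",
                     esc(cp$idisk_id), esc(cp$preferred_name))
    if (!is.na(cp$cui)) props <- paste0(props, sprintf(", cui: '%s'",
                                                       esc(cp$cui)))
    for (k in names(cp$attributes))
      props <- paste0(props, sprintf(", %s: '%s'", k,
                                     esc(cp$attributes[[k]])))
    stmts <- c(stmts, sprintf("MERGE (n:%s {%s});", cp$concept_type, props))
  }
  tdf <- kg_triples_df(g)
  for (i in seq_len(nrow(tdf))) {
    stmts <- c(stmts, sprintf(
      "MATCH (h {idisk_id: '%s'}), (t {idisk_id: '%s'}) MERGE (h)-[:%s]->(t);",
      esc(tdf$head_id[i]), esc(tdf$tail_id[i]), tdf$relation[i]))
  }
  stmts
}
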